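# Interval utilities shared across the pipeline.
#
# All internal coordinates are 0-based half-open [start, end); conversion to
# and from 1-based inclusive happens only at format boundaries (GTF, the
# per-call report table). BED is already 0-based half-open.

STRANDS <- c("+", "-")

check_strand <- function(strand, what = "record") {
  bad <- !strand %in% STRANDS
  if (any(bad)) {
    abort(sprintf("%s with invalid strand value(s): %s", what,
                  paste(unique(strand[bad]), collapse = ", ")))
  }
  invisible(strand)
}

#' Merge genomic intervals into minimal disjoint coverage blocks
#'
#' Computes the minimal sorted set of disjoint intervals whose union equals
#' the union of the input. Adjacent (bookended) intervals *are* merged: this
#' models covered bases, not read connectivity (reads touching end-to-start
#' share zero bases and stay in separate fragments, but their covered bases
#' form one block).
#'
#' @param blocks A data frame with `start` and `end` columns, 0-based
#'   half-open, all on one chromosome and strand.
#' @return A tibble with `start` and `end`, sorted, disjoint, non-adjacent.
#' @examples
#' merge_coverage(data.frame(start = c(100, 150), end = c(200, 300)))
#' merge_coverage(data.frame(start = c(100, 200), end = c(200, 300)))
#' @export
merge_coverage <- function(blocks) {
  m <- merge_runs(blocks$start, blocks$end, bookended = TRUE)
  tibble(start = m$start, end = m$end)
}

# Vectorised interval merge. With bookended = TRUE intervals touching
# end-to-start coalesce (coverage semantics); with FALSE a >= 1 bp overlap is
# required to join (read-merge semantics). Also returns the group index of
# each input interval in its original order.
merge_runs <- function(start, end, bookended = TRUE) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(list(start = integer(), end = integer(), group = integer()))
  }
  if (any(start >= end)) abort("interval with start >= end")
  ord <- order(start, end)
  s <- start[ord]; e <- end[ord]
  prev_max <- c(-Inf, cummax(as.numeric(e))[-length(e)])
  new_run <- if (bookended) s > prev_max else s >= prev_max
  grp <- cumsum(new_run)
  group <- integer(length(s))
  group[ord] <- grp
  list(
    start = as.integer(tapply(s, grp, min)),
    end = as.integer(tapply(e, grp, max)),
    group = group
  )
}

# Natural ("version-style") order of sequence names: chr2 before chr10.
natural_chrom_order <- function(x) {
  ux <- unique(x)
  num <- suppressWarnings(as.numeric(stringr::str_extract(ux, "[0-9]+(\\.[0-9]+)?")))
  prefix <- stringr::str_replace(ux, "[0-9].*$", "")
  key <- order(prefix, num, ux, na.last = TRUE)
  match(x, ux[key])
}

# Round half away from zero at `digits` decimals (presentation rounding used
# by the run-summary tables; base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# tibble of intervals -> GRanges (1-based inclusive internally to GRanges)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}
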