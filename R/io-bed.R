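#' Write NTR calls (or any blocked intervals) as BED12
#'
#' One BED12 line per call: `chromStart`/`chromEnd` are the call span,
#' blocks are the merged exonic coverage of the call's reads, the score is
#' the junction count capped at 1000, and the name is the call id. BED is
#' 0-based half-open, matching the internal convention, so no coordinate
#' shift is applied.
#'
#' @param calls A tibble with `chrom`, `start`, `end`, `strand`, an id
#'   column (`ntr_id` or `name`), coverage list-columns
#'   `cov_starts`/`cov_ends`, and `n_junctions`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ntr_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- calls$ntr_id %||% calls$name
  if (is.null(name)) abort("calls need an `ntr_id` or `name` column")
  if (any(lengths(calls$cov_starts) == 0L)) {
    abort("call with zero fragments / empty coverage cannot be written")
  }
  score <- pmin(calls$n_junctions %||% rep(0L, nrow(calls)), 1000L)
  lines <- pmap(
    list(calls$chrom, calls$start, calls$end, name, score, calls$strand,
         calls$cov_starts, calls$cov_ends),
    function(chrom, start, end, name, score, strand, cs, ce) {
      stopifnot(cs[1] == start, ce[length(ce)] == end)
      paste(chrom, start, end, name, score, strand, start, end, "0",
            length(cs),
            paste0(paste(ce - cs, collapse = ","), ","),
            paste0(paste(cs - start, collapse = ","), ","),
            sep = "\t")
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a BED12 file of blocked intervals
#'
#' @param path Path to a BED12 file (no header). An empty file yields an
#'   empty tibble.
#' @return A tibble with `name`, `chrom`, `start`, `end`, `strand`, `score`,
#'   and coverage list-columns `cov_starts`/`cov_ends`, 0-based half-open.
#' @export
read_ntr_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  empty <- tibble(name = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), score = integer(),
                  cov_starts = list(), cov_ends = list())
  if (file.size(path) == 0L) return(empty)
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) abort("expected 12 BED columns")
  parse_csv <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1]])
  sizes <- map(raw[[11]], parse_csv)
  offsets <- map(raw[[12]], parse_csv)
  tibble(
    name = as.character(raw[[4]]),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = as.character(raw[[6]]),
    score = as.integer(raw[[5]]),
    cov_starts = map2(raw[[2]], offsets, function(s, o) as.integer(s + o)),
    cov_ends = pmap(list(raw[[2]], offsets, sizes),
                    function(s, o, z) as.integer(s + o + z))
  )
}

#' Write splice junctions as BED6
#'
#' One line per junction site: the interval is the intron, the name is
#' `donor-acceptor` (0-based intron boundaries) and the score is the number
#' of supporting reads.
#'
#' @param junctions Junction tibble from [extract_junctions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  lines <- sprintf("%s\t%d\t%d\t%d-%d\t%d\t%s",
                   junctions$chrom, junctions$intron_start,
                   junctions$intron_end, junctions$intron_start,
                   junctions$intron_end, junctions$support, junctions$strand)
  writeLines(lines, path)
  invisible(path)
}
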