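#' Build fragments from uniquely mapped reads
#'
#' A *fragment* is a maximal set of same-strand reads in which adjacent
#' reads overlap by one or more base pairs at their ends; a single spliced
#' read is a fragment by itself. Bookended reads (zero shared bases) never
#' merge. Each fragment carries the union of its member reads' splice
#' junctions and the merged exonic coverage of their aligned blocks.
#'
#' By default connectivity uses the read *span* (first to last aligned
#' base, introns included), so a read lying entirely inside another read's
#' intron joins that fragment. With `connect = "blocks"` reads are linked
#' only when their aligned blocks themselves share bases; a spliced read
#' still holds its own blocks together.
#'
#' @param reads Read tibble from [read_alignments()].
#' @param connect `"span"` (default) or `"blocks"`; see Details.
#' @return A tibble with one row per fragment, sorted by (`chrom`,
#'   `strand`, `start`): span columns, `read_count`, `n_junctions`, a
#'   `junctions` list-column of per-site tibbles (`intron_start`,
#'   `intron_end`, `support`), and merged coverage list-columns
#'   `cov_starts`/`cov_ends` whose hull equals the span.
#' @export
build_fragments <- function(reads, connect = c("span", "blocks")) {
  connect <- match.arg(connect)
  check_strand(reads$strand, "read")
  if (nrow(reads) == 0L) return(empty_fragments())
  reads <- arrange(reads, .data$chrom, .data$strand, .data$start, .data$end)
  grouped <- reads |>
    group_by(.data$chrom, .data$strand) |>
    mutate(frag = if (connect == "span") {
      merge_runs(.data$start, .data$end, bookended = FALSE)$group
    } else {
      block_components(.data$block_starts, .data$block_ends)
    }) |>
    ungroup()
  fragments <- grouped |>
    summarise(
      read_count = n(),
      junctions = list(collect_junctions(.data$block_starts, .data$block_ends)),
      cov = list(merge_runs(unlist(.data$block_starts),
                            unlist(.data$block_ends), bookended = TRUE)),
      start = min(.data$start),
      end = max(.data$end),
      .by = c("chrom", "strand", "frag")
    ) |>
    mutate(
      n_junctions = map_int(.data$junctions, nrow),
      cov_starts = map(.data$cov, "start"),
      cov_ends = map(.data$cov, "end")
    ) |>
    select("chrom", "start", "end", "strand", "read_count", "n_junctions",
           "junctions", "cov_starts", "cov_ends")
  arrange(fragments, natural_chrom_order(.data$chrom), .data$strand,
          .data$start)
}

empty_fragments <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), read_count = integer(),
         n_junctions = integer(), junctions = list(), cov_starts = list(),
         cov_ends = list())
}

# Distinct junction sites implied by a set of reads' blocks, with read
# support per site.
collect_junctions <- function(block_starts, block_ends) {
  intron_start <- unlist(map(block_ends, function(x) x[-length(x)]))
  intron_end <- unlist(map(block_starts, function(x) x[-1]))
  if (is.null(intron_start) || length(intron_start) == 0L) {
    return(tibble(intron_start = integer(), intron_end = integer(),
                  support = integer()))
  }
  tibble(intron_start = as.integer(intron_start),
         intron_end = as.integer(intron_end)) |>
    count(.data$intron_start, .data$intron_end, name = "support") |>
    arrange(.data$intron_start, .data$intron_end)
}

# Connected components of reads linked through >= 1 bp block overlaps
# (union-find over reads, with block runs as the linking structure).
block_components <- function(block_starts, block_ends) {
  n <- length(block_starts)
  read_of_block <- rep.int(seq_len(n), lengths(block_starts))
  bs <- unlist(block_starts); be <- unlist(block_ends)
  runs <- merge_runs(bs, be, bookended = FALSE)$group
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in split(read_of_block, runs)) {
    anchor <- find(r[1])
    for (j in r[-1]) {
      rj <- find(j)
      if (rj != anchor) parent[rj] <- anchor
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
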