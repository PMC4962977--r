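# Brute-force oracles, deliberately implemented along different routes than
# the package (pairwise graphs + igraph components, per-bp bitmaps, O(n^2)
# scans) so agreement is informative.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise >= 1 bp span-overlap graph on one (chrom, strand); fragments are
# its connected components.
oracle_fragments <- function(reads) {
  split(reads, paste(reads$chrom, reads$strand)) |>
    lapply(function(g) {
      n <- nrow(g)
      ov <- outer(g$start, g$end, `<`) & outer(g$end, g$start, `>`)
      graph <- igraph::graph_from_adjacency_matrix(ov, mode = "max")
      comp <- igraph::components(graph)$membership
      tibble::tibble(
        chrom = g$chrom[1], strand = g$strand[1],
        start = tapply(g$start, comp, min),
        end = tapply(g$end, comp, max),
        read_count = as.integer(table(comp))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(chrom, strand, start) |>
    dplyr::mutate(start = as.integer(start), end = as.integer(end))
}

# Transitive closure of pairwise linkage gap <= d2 (or < d2).
oracle_clusters <- function(frags, d2, strict = FALSE) {
  split(frags, paste(frags$chrom, frags$strand)) |>
    lapply(function(g) {
      gap <- pmax(outer(g$start, g$end, `-`), t(outer(g$start, g$end, `-`)))
      gap[gap < 0] <- 0
      linked <- if (strict) gap < d2 else gap <= d2
      graph <- igraph::graph_from_adjacency_matrix(linked, mode = "max")
      comp <- igraph::components(graph)$membership
      tibble::tibble(
        chrom = g$chrom[1], strand = g$strand[1],
        start = as.integer(tapply(g$start, comp, min)),
        end = as.integer(tapply(g$end, comp, max)),
        n_fragments = as.integer(table(comp))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(chrom, strand, start)
}

# Per-bp bitmap union of blocks on one chromosome.
oracle_coverage <- function(start, end) {
  lo <- min(start); hi <- max(end)
  bits <- logical(hi - lo)
  for (i in seq_along(start)) {
    bits[(start[i] - lo + 1):(end[i] - lo)] <- TRUE
  }
  r <- rle(bits)
  stops <- cumsum(r$lengths)
  starts <- c(0L, head(stops, -1))
  tibble::tibble(start = lo + starts[r$values], end = lo + stops[r$values])
}

# O(n * m) distance scan: 0 on overlap, else minimal half-open gap, Inf if
# no qualifying transcript.
oracle_distance <- function(intervals, annotation, same_strand = TRUE) {
  vapply(seq_len(nrow(intervals)), function(i) {
    f <- intervals[i, ]
    best <- Inf
    for (j in seq_len(nrow(annotation))) {
      a <- annotation[j, ]
      if (a$chrom != f$chrom) next
      if (same_strand && a$strand != f$strand) next
      d <- if (a$start < f$end && a$end > f$start) 0
        else max(a$start - f$end, f$start - a$end)
      best <- min(best, d)
    }
    best
  }, numeric(1))
}

# Per-read overlap scan for expression counting.
oracle_count <- function(call, reads) {
  sum(vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    r$chrom == call$chrom && r$strand == call$strand &&
      r$start < call$end && r$end > call$start
  }, logical(1)))
}
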