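#' Discovery parameters
#'
#' Tuning knobs of the NTR discovery workflow. `d1` is the exclusion
#' distance: fragments at most `d1` bp from any annotated transcript
#' (same strand by default) are discarded as possible extensions of known
#' genes. `d2` is the linkage distance: consecutive same-strand fragments
#' with a gap of at most `d2` bp chain into one cluster. A cluster becomes
#' an NTR call only with at least `min_junctions` distinct splice junction
#' sites; junctionless one-fragment clusters longer than
#' `singleton_min_len` bp are reported separately as singletons, never
#' called.
#'
#' @param d1 Annotation exclusion distance in bp (default 1000).
#' @param d2 Fragment linkage distance in bp (default 5000).
#' @param min_junctions Minimum distinct junction sites per call (default 2).
#' @param singleton_min_len Minimum span of a reported singleton in bp
#'   (default 50; the rule is strictly greater).
#' @param same_strand_only Restrict annotation exclusion and secondary
#'   subtraction to same-strand transcripts (default `TRUE`); antisense
#'   overlap then keeps a fragment.
#' @param strict_d2 Link fragments only when the gap is strictly below
#'   `d2` (default `FALSE`: gap <= `d2` links).
#' @param min_junction_support Minimum reads supporting a junction site for
#'   it to count (default 1).
#' @return A `discovery_params` list.
#' @export
discovery_params <- function(d1 = 1000, d2 = 5000, min_junctions = 2,
                             singleton_min_len = 50,
                             same_strand_only = TRUE, strict_d2 = FALSE,
                             min_junction_support = 1) {
  stopifnot(d1 >= 0, d2 >= 0, min_junctions >= 0, singleton_min_len >= 0,
            min_junction_support >= 1)
  structure(
    list(d1 = as.numeric(d1), d2 = as.numeric(d2),
         min_junctions = as.integer(min_junctions),
         singleton_min_len = as.numeric(singleton_min_len),
         same_strand_only = isTRUE(same_strand_only),
         strict_d2 = isTRUE(strict_d2),
         min_junction_support = as.integer(min_junction_support)),
    class = "discovery_params"
  )
}

#' Distance from intervals to the nearest annotated transcript
#'
#' Returns 0 for an interval overlapping (or bookending) a qualifying
#' transcript, otherwise the minimal gap in bp (`next start - previous end`
#' under half-open arithmetic) to the nearest transcript on either side;
#' `Inf` when no qualifying transcript exists (e.g. only antisense
#' transcripts under `same_strand = TRUE`).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `strand` (e.g.
#'   fragments).
#' @param annotation Annotation tibble from [read_annotation()].
#' @param same_strand Only consider same-strand transcripts (default
#'   `TRUE`).
#' @return Numeric vector of distances, one per input row.
#' @export
distance_to_annotation <- function(intervals, annotation,
                                   same_strand = TRUE) {
  if (nrow(intervals) == 0L) return(numeric())
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(rep(Inf, nrow(intervals)))
  }
  q <- intervals_to_granges(intervals)
  s <- annotation_granges(annotation)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, s, ignore.strand = !same_strand)
  )
  out <- rep(Inf, nrow(intervals))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Partition fragments by annotation proximity (D1 filter)
#'
#' Fragments overlapping an annotated transcript are flagged
#' `in_annotation`; fragments within `d1` bp of one (`0 < distance <= d1`)
#' are flagged `proximal`; the rest are `kept` for clustering. The three
#' statuses partition the input.
#'
#' @param fragments Fragment tibble from [build_fragments()].
#' @param annotation Primary annotation tibble.
#' @param params [discovery_params()].
#' @return The fragment tibble with `dist_annotation` and `status`
#'   (`"kept"`, `"in_annotation"`, `"proximal"`) columns added.
#' @export
filter_fragments <- function(fragments, annotation,
                             params = discovery_params()) {
  d <- distance_to_annotation(fragments, annotation,
                              same_strand = params$same_strand_only)
  fragments |>
    mutate(
      dist_annotation = d,
      status = case_when(
        d == 0 ~ "in_annotation",
        d <= params$d1 ~ "proximal",
        .default = "kept"
      )
    )
}

#' Chain fragments into clusters (D2 linkage)
#'
#' Consecutive same-strand fragments whose gap is at most `d2` bp (strictly
#' below `d2` with `strict_d2`) are linked; a maximal chain of linked
#' fragments forms a cluster. Each cluster records the union of its
#' fragments' junction sites and merged coverage.
#'
#' @param fragments Fragment tibble (typically the `kept` rows of
#'   [filter_fragments()]).
#' @param params [discovery_params()].
#' @return A tibble with one row per cluster: span columns, `n_fragments`,
#'   `read_count`, `n_junctions`, list-columns `junctions`,
#'   `frag_starts`/`frag_ends`, `cov_starts`/`cov_ends`.
#' @export
cluster_fragments <- function(fragments, params = discovery_params()) {
  if (nrow(fragments) == 0L) return(empty_clusters())
  fragments <- arrange(fragments, .data$chrom, .data$strand, .data$start,
                       .data$end)
  grouped <- fragments |>
    group_by(.data$chrom, .data$strand) |>
    mutate(cl = {
      prev_end <- c(-Inf, cummax(as.numeric(.data$end))[-n()])
      gap <- .data$start - prev_end
      linked <- if (params$strict_d2) gap < params$d2 else gap <= params$d2
      cumsum(!linked)
    }) |>
    ungroup()
  clusters <- grouped |>
    summarise(
      n_fragments = n(),
      read_count = sum(.data$read_count),
      junctions = list(union_junctions(.data$junctions)),
      frag_starts = list(.data$start),
      frag_ends = list(.data$end),
      cov = list(merge_runs(unlist(.data$cov_starts),
                            unlist(.data$cov_ends), bookended = TRUE)),
      start = min(.data$start),
      end = max(.data$end),
      .by = c("chrom", "strand", "cl")
    ) |>
    mutate(
      n_junctions = map_int(
        .data$junctions,
        function(j) sum(j$support >= params$min_junction_support)
      ),
      cov_starts = map(.data$cov, "start"),
      cov_ends = map(.data$cov, "end")
    ) |>
    select("chrom", "start", "end", "strand", "n_fragments", "read_count",
           "n_junctions", "junctions", "frag_starts", "frag_ends",
           "cov_starts", "cov_ends")
  arrange(clusters, natural_chrom_order(.data$chrom), .data$strand,
          .data$start)
}

empty_clusters <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), n_fragments = integer(),
         read_count = integer(), n_junctions = integer(), junctions = list(),
         frag_starts = list(), frag_ends = list(), cov_starts = list(),
         cov_ends = list())
}

union_junctions <- function(junction_list) {
  out <- list_rbind(junction_list)
  if (nrow(out) == 0L) return(out)
  out |>
    summarise(support = sum(.data$support),
              .by = c("intron_start", "intron_end")) |>
    arrange(.data$intron_start, .data$intron_end)
}

#' Filter clusters by junction support and flag singletons
#'
#' Clusters with at least `min_junctions` distinct junction sites become
#' candidates. Among the rest, junctionless one-fragment clusters whose
#' span exceeds `singleton_min_len` bp are flagged `singleton` (reported
#' but never called); everything else is `rejected_few_junctions`.
#'
#' @param clusters Cluster tibble from [cluster_fragments()].
#' @param params [discovery_params()].
#' @return The cluster tibble with a `status` column added.
#' @export
filter_clusters <- function(clusters, params = discovery_params()) {
  clusters |>
    mutate(status = case_when(
      .data$n_junctions >= params$min_junctions ~ "candidate",
      .data$n_fragments == 1L & .data$n_junctions == 0L &
        (.data$end - .data$start) > params$singleton_min_len ~ "singleton",
      .default = "rejected_few_junctions"
    ))
}

#' Subtract secondary annotations and emit NTR calls
#'
#' A candidate cluster is removed when its span overlaps any qualifying
#' transcript of the secondary annotation by >= 1 bp (same strand under
#' `same_strand_only`; this is an identity/overlap test, not the D1
#' proximity test). Survivors become NTR calls with ids assigned in genomic
#' order (natural chromosome order, then start).
#'
#' @param clusters Status-annotated cluster tibble from
#'   [filter_clusters()]; only `candidate` rows are considered.
#' @param secondary Secondary annotation tibble, or `NULL`/empty for no
#'   subtraction.
#' @param params [discovery_params()].
#' @return A list with `calls` (NTR call tibble: `ntr_id`, span columns,
#'   `read_count`, `n_fragments`, `n_junctions`, `exonic_length`, coverage
#'   and junction list-columns) and `clusters` (input tibble with
#'   candidate rows relabelled `ntr` or `annotated_secondary`).
#' @export
subtract_known <- function(clusters, secondary = NULL,
                           params = discovery_params()) {
  is_cand <- clusters$status == "candidate"
  removed <- rep(FALSE, nrow(clusters))
  if (!is.null(secondary) && nrow(secondary) > 0L && any(is_cand)) {
    q <- intervals_to_granges(clusters[is_cand, ])
    s <- annotation_granges(secondary)
    n_ov <- suppressWarnings(GenomicRanges::countOverlaps(
      q, s, minoverlap = 1L, ignore.strand = !params$same_strand_only
    ))
    removed[is_cand] <- n_ov > 0L
  }
  clusters$status[is_cand & removed] <- "annotated_secondary"
  clusters$status[is_cand & !removed] <- "ntr"
  calls <- clusters |>
    filter(.data$status == "ntr") |>
    arrange(natural_chrom_order(.data$chrom), .data$start, .data$end) |>
    mutate(
      ntr_id = paste0("NTR", row_number()),
      exonic_length = map_int(map2(.data$cov_starts, .data$cov_ends,
                                   function(s, e) e - s), sum)
    ) |>
    select("ntr_id", "chrom", "start", "end", "strand", "read_count",
           "n_fragments", "n_junctions", "exonic_length", "junctions",
           "cov_starts", "cov_ends")
  list(calls = calls, clusters = clusters)
}

#' Run the full NTR discovery workflow
#'
#' Composes the pipeline: read alignments, build fragments, exclude
#' annotation-overlapping and annotation-proximal fragments (D1), chain the
#' remainder into clusters (D2), apply the junction and singleton filters,
#' and subtract secondary annotations. Deterministic for fixed inputs and
#' parameters.
#'
#' @param alignments A read tibble from [read_alignments()], or one or more
#'   SAM/BAM paths.
#' @param primary Primary annotation: tibble from [read_annotation()] or a
#'   GTF path.
#' @param secondary Optional secondary annotation(s): tibble, GTF path, or
#'   a list/vector of either. Multiple annotations are pooled.
#' @param params [discovery_params()].
#' @param ... Passed to [read_alignments()] when `alignments` are paths.
#' @return An object of class `ntr_discovery` with elements `calls`,
#'   `clusters`, `fragments`, `report` (one-row count ledger), and
#'   `params`. Use [tidy()] for the calls, [glance()] for the ledger.
#' @export
run_discovery <- function(alignments, primary, secondary = NULL,
                          params = discovery_params(), ...) {
  reads <- if (is.data.frame(alignments)) alignments else
    list_rbind(map(alignments, read_alignments, ...))
  primary <- if (is.data.frame(primary) || is.null(primary)) primary else
    read_annotation(primary)
  secondary <- pool_annotations(secondary)

  fragments <- build_fragments(reads)
  fragments <- filter_fragments(fragments, primary, params)
  kept <- filter(fragments, .data$status == "kept")
  clusters <- cluster_fragments(kept, params)
  clusters <- filter_clusters(clusters, params)
  sub <- subtract_known(clusters, secondary, params)
  clusters <- sub$clusters

  report <- tibble(
    n_reads = nrow(reads),
    n_fragments_total = nrow(fragments),
    n_fragments_in_annotation = sum(fragments$status == "in_annotation"),
    n_fragments_proximal_d1 = sum(fragments$status == "proximal"),
    n_fragments_clustered = nrow(kept),
    n_clusters = nrow(clusters),
    n_clusters_junction_filtered =
      sum(clusters$status == "rejected_few_junctions"),
    n_singletons = sum(clusters$status == "singleton"),
    n_removed_secondary = sum(clusters$status == "annotated_secondary"),
    n_ntr_final = nrow(sub$calls)
  )
  structure(
    list(calls = sub$calls, clusters = clusters, fragments = fragments,
         report = report, params = params),
    class = "ntr_discovery"
  )
}

pool_annotations <- function(secondary) {
  if (is.null(secondary)) return(NULL)
  if (is.data.frame(secondary)) return(secondary)
  list_rbind(map(as.list(secondary), function(x) {
    if (is.data.frame(x)) x else read_annotation(x)
  }))
}

#' @export
print.ntr_discovery <- function(x, ...) {
  r <- x$report
  cat("<ntr_discovery>\n")
  cat(sprintf("  %d reads -> %d fragments (%d in annotation, %d within D1=%g, %d clustered)\n",
              r$n_reads, r$n_fragments_total, r$n_fragments_in_annotation,
              r$n_fragments_proximal_d1, x$params$d1,
              r$n_fragments_clustered))
  cat(sprintf("  %d clusters at D2=%g: %d junction-filtered, %d singletons, %d in secondary annotation\n",
              r$n_clusters, x$params$d2, r$n_clusters_junction_filtered,
              r$n_singletons, r$n_removed_secondary))
  cat(sprintf("  %d NTR calls (>= %d junction sites)\n", r$n_ntr_final,
              x$params$min_junctions))
  invisible(x)
}

#' @rdname run_discovery
#' @param x An `ntr_discovery` object.
#' @method tidy ntr_discovery
#' @export
tidy.ntr_discovery <- function(x, ...) x$calls

#' @rdname run_discovery
#' @method glance ntr_discovery
#' @export
glance.ntr_discovery <- function(x, ...) x$report

#' Write discovery outputs to files
#'
#' Writes `<prefix>.ntr.bed` (BED12 calls), `<prefix>.report.tsv` (the
#' count ledger) and `<prefix>.table2.tsv` (per-call table with 1-based
#' inclusive start/end: id, chrom, start, end, reads, fragments, strand,
#' junctions).
#'
#' @param x An `ntr_discovery` object.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_discovery <- function(x, prefix) {
  paths <- paste0(prefix, c(".ntr.bed", ".report.tsv", ".table2.tsv"))
  write_ntr_bed(x$calls, paths[1])
  write.table(x$report, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tab <- x$calls |>
    transmute(id = .data$ntr_id, chrom = .data$chrom,
              start = .data$start + 1L, end = .data$end,
              reads = .data$read_count, fragments = .data$n_fragments,
              strand = .data$strand, junctions = .data$n_junctions)
  write.table(tab, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
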