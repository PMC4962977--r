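#' Total reads across sequencing runs
#'
#' Sums per-run read counts (in millions) for one stage, reported at one
#' decimal with half-up rounding to match tabular presentation.
#'
#' @param per_run Non-empty numeric vector of per-run read counts in
#'   millions.
#' @return The total in millions, one decimal.
#' @examples
#' total_reads(c(114.4, 52.5, 73.5))  # 240.4
#' @export
total_reads <- function(per_run) {
  if (length(per_run) == 0L) abort("no per-run read counts supplied")
  if (any(per_run < 0)) abort("read counts must be non-negative")
  round_half_up(sum(per_run), 1)
}

#' Mapped-read percentage
#'
#' `100 * mapped / total`, rounded half-up to one decimal. Scale-invariant
#' in its two arguments.
#'
#' @param mapped Mapped reads (millions).
#' @param total Total reads (millions); must be positive.
#' @return Percentage at one decimal.
#' @examples
#' mapped_pct(76.3, 228.0)  # 33.5
#' @export
mapped_pct <- function(mapped, total) {
  if (any(total <= 0)) abort("total reads must be positive")
  if (any(mapped < 0) || any(mapped > total)) {
    abort("mapped reads must lie in [0, total]")
  }
  round_half_up(100 * mapped / total, 1)
}

#' Per-stage sequencing summary
#'
#' Builds a per-stage summary table (total reads, mapped percentage) from
#' raw per-run counts and mapped/unique totals, all in millions of reads.
#'
#' @param stages Tibble with columns `stage`, `per_run` (list-column of
#'   per-run counts), `mapped_reads`, `unique_reads`.
#' @return The input with `total_reads` and `mapped_pct` columns added.
#' @export
stage_summary <- function(stages) {
  out <- stages |>
    mutate(
      total_reads = map_dbl(.data$per_run, total_reads),
      mapped_pct = mapped_pct(.data$mapped_reads, .data$total_reads)
    )
  bad <- out$unique_reads > out$mapped_reads |
    out$mapped_reads > out$total_reads
  if (any(bad)) {
    abort("expected unique_reads <= mapped_reads <= total_reads")
  }
  out
}

#' Summarise mapping statistics directly from alignment files
#'
#' Counts records, mapped reads, and uniquely mapped reads (per the same
#' uniqueness policy as [read_alignments()]) in one or more SAM/BAM files,
#' one row per file.
#'
#' @param paths SAM/BAM paths.
#' @param labels Stage labels, one per path (defaults to file names).
#' @param mapq_min MAPQ fallback threshold for uniqueness.
#' @return Tibble with `stage`, `total_reads`, `mapped_reads`,
#'   `unique_reads`, `mapped_pct` (reads, not millions).
#' @export
alignment_stats <- function(paths, labels = basename(paths),
                            mapq_min = 20L) {
  rows <- map2(paths, labels, function(path, label) {
    bam <- as_bam(path)
    total <- Rsamtools::countBam(bam)$records
    mapped_param <- Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE))
    mapped <- Rsamtools::countBam(bam, param = mapped_param)$records
    unique <- nrow(read_alignments(path, mapq_min = mapq_min))
    tibble(stage = label, total_reads = total, mapped_reads = mapped,
           unique_reads = unique,
           mapped_pct = if (total > 0) mapped_pct(mapped, total) else NA_real_)
  })
  list_rbind(rows)
}
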