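#' Count reads overlapping each NTR call
#'
#' A read is assigned to a call when its span overlaps the call span by at
#' least one base pair on the same strand (matching fragment connectivity,
#' which also uses spans; set `by = "blocks"` to require overlap with the
#' aligned blocks instead).
#'
#' @param calls NTR call tibble (`ntr_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param reads Read tibble from [read_alignments()].
#' @param by `"span"` (default) or `"blocks"`.
#' @return The calls with a `count` column appended.
#' @export
count_reads <- function(calls, reads, by = c("span", "blocks")) {
  by <- match.arg(by)
  if (nrow(calls) == 0L) return(mutate(calls, count = integer()))
  q <- intervals_to_granges(calls)
  if (nrow(reads) == 0L) return(mutate(calls, count = 0L))
  if (by == "span") {
    s <- intervals_to_granges(reads)
    counts <- suppressWarnings(
      GenomicRanges::countOverlaps(q, s, minoverlap = 1L,
                                   ignore.strand = FALSE))
  } else {
    blocks <- tibble(
      chrom = rep.int(reads$chrom, reads$n_blocks),
      start = unlist(reads$block_starts),
      end = unlist(reads$block_ends),
      strand = rep.int(reads$strand, reads$n_blocks),
      read = rep.int(seq_len(nrow(reads)), reads$n_blocks)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      q, intervals_to_granges(blocks), minoverlap = 1L,
      ignore.strand = FALSE))
    pairs <- unique(tibble(q = S4Vectors::queryHits(hits),
                           r = blocks$read[S4Vectors::subjectHits(hits)]))
    counts <- tabulate(pairs$q, nbins = nrow(calls))
  }
  mutate(calls, count = as.integer(counts))
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `fpkm = count / ((exonic_length / 1e3) * (library_size / 1e6))`. Linear
#' in the count, inverse-linear in both the exonic length and the library
#' size.
#'
#' @param count Read count(s) assigned to the feature.
#' @param exonic_length Feature length in bp (sum of merged coverage
#'   blocks); must be positive.
#' @param library_size Total mapped reads in the library; must be positive.
#' @return Numeric FPKM value(s).
#' @examples
#' fpkm(1000, 2000, 1e7)  # 50
#' @export
fpkm <- function(count, exonic_length, library_size) {
  if (any(exonic_length <= 0)) abort("exonic_length must be positive")
  if (any(library_size <= 0)) abort("library_size must be positive")
  count / ((exonic_length / 1e3) * (library_size / 1e6))
}

#' FPKM matrix of NTR calls across stages
#'
#' Counts reads per call in each stage's alignments and converts to FPKM
#' using each stage's mapped-read library size.
#'
#' @param calls NTR call tibble with `exonic_length`.
#' @param stage_reads Named list of read tibbles (or SAM/BAM paths), one
#'   per stage, in stage order.
#' @param library_sizes Optional named numeric vector of mapped-read totals
#'   per stage; defaults to the number of reads in each stage's tibble.
#' @return A tibble with `ntr_id` and one FPKM column per stage, carrying
#'   the library sizes in the `library_sizes` attribute.
#' @export
fpkm_matrix <- function(calls, stage_reads, library_sizes = NULL) {
  if (is.null(names(stage_reads)) || anyNA(names(stage_reads))) {
    abort("stage_reads must be a named list (stage labels)")
  }
  stage_reads <- map(stage_reads, function(x) {
    if (is.data.frame(x)) x else read_alignments(x)
  })
  if (is.null(library_sizes)) {
    library_sizes <- vapply(stage_reads, nrow, integer(1))
  }
  library_sizes <- library_sizes[names(stage_reads)]
  if (anyNA(library_sizes) || any(library_sizes <= 0)) {
    abort("one positive library size per stage is required")
  }
  out <- tibble(ntr_id = calls$ntr_id)
  for (stage in names(stage_reads)) {
    cnt <- count_reads(calls, stage_reads[[stage]])$count
    out[[stage]] <- fpkm(cnt, calls$exonic_length, library_sizes[[stage]])
  }
  attr(out, "library_sizes") <- library_sizes
  out
}

#' Fold change of expression against a baseline stage
#'
#' Divides every stage column by the baseline column, row-wise. Rows whose
#' baseline value is zero are flagged `baseline_undefined` and their ratios
#' set to `NA` rather than infinity (an NTR not expressed at the baseline
#' stage has no defined fold change).
#'
#' @param mat FPKM tibble from [fpkm_matrix()] (`ntr_id` plus stage
#'   columns).
#' @param baseline Name of the baseline stage column.
#' @return A tibble with `ntr_id`, `baseline_undefined`, and one ratio
#'   column per stage.
#' @export
fold_change <- function(mat, baseline) {
  stages <- setdiff(names(mat), "ntr_id")
  if (!baseline %in% stages) {
    abort(sprintf("unknown baseline stage: %s", baseline))
  }
  base <- mat[[baseline]]
  undef <- base == 0
  out <- tibble(ntr_id = mat$ntr_id, baseline_undefined = undef)
  for (stage in stages) {
    out[[stage]] <- ifelse(undef, NA_real_, mat[[stage]] / base)
  }
  out
}

#' Per-row standard scaling of an expression matrix
#'
#' Centres and scales each row (NTR) to mean 0 and unit standard deviation
#' across stages, the transformation used when clustering expression
#' profiles so that NTRs of very different absolute levels become
#' comparable. Constant rows map to all zeros.
#'
#' @param mat FPKM tibble (`ntr_id` plus >= 2 stage columns).
#' @param denom `"n-1"` (default, sample standard deviation) or `"n"`.
#' @return A tibble of the same shape with scaled values.
#' @export
scale_rows <- function(mat, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  stages <- setdiff(names(mat), "ntr_id")
  if (length(stages) < 2L) abort("need at least two stage columns")
  m <- as.matrix(mat[stages])
  mu <- rowMeans(m)
  centred <- m - mu
  s <- sqrt(rowSums(centred^2) /
              (if (denom == "n-1") ncol(m) - 1L else ncol(m)))
  scaled <- centred / ifelse(s == 0, 1, s)
  scaled[s == 0, ] <- 0
  out <- as_tibble(scaled)
  bind_cols(mat["ntr_id"], out)
}

#' Classify a four-stage expression profile
#'
#' Deterministic rule set over the ordered stages (1-cell, 16-cell,
#' 512-cell/MBT, 50%-epiboly), applied in priority order:
#' \describe{
#'   \item{post_mbt_up}{final stage exceeds the third (MBT) stage;}
#'   \item{mbt_peak}{third stage is the strict maximum;}
#'   \item{maternal_decay}{first stage is the strict maximum and the
#'     profile is non-increasing within tolerance;}
#'   \item{low_flat}{all values below `low_threshold` and relative range
#'     (max - min relative to max) within tolerance;}
#'   \item{other}{everything else.}
#' }
#' Every non-negative 4-vector maps to exactly one class.
#'
#' @param x Numeric vector of 4 FPKM values in stage order.
#' @param low_threshold FPKM ceiling for `low_flat` (default 1).
#' @param tol Relative tolerance for "non-increasing" and "flat"
#'   (default 0.1).
#' @return A single class label.
#' @export
classify_profile <- function(x, low_threshold = 1, tol = 0.1) {
  if (length(x) != 4L) abort("profile classification needs exactly 4 stages")
  if (any(is.na(x)) || any(x < 0)) abort("FPKM values must be non-negative")
  if (x[4] > x[3]) return("post_mbt_up")
  if (x[3] > max(x[-3])) return("mbt_peak")
  non_increasing <- all(diff(x) <= tol * head(x, -1))
  if (x[1] > max(x[-1]) && non_increasing) return("maternal_decay")
  rng_ok <- max(x) == 0 || (max(x) - min(x)) <= tol * max(x)
  if (all(x < low_threshold) && rng_ok) return("low_flat")
  "other"
}

#' @rdname classify_profile
#' @param mat FPKM tibble (`ntr_id` plus 4 stage columns).
#' @return For `classify_profiles()`: the tibble with a `class` column.
#' @export
classify_profiles <- function(mat, low_threshold = 1, tol = 0.1) {
  stages <- setdiff(names(mat), "ntr_id")
  m <- as.matrix(mat[stages])
  mutate(mat, class = apply(m, 1, classify_profile,
                            low_threshold = low_threshold, tol = tol))
}
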