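#' Simulation configuration
#'
#' Parameters of the synthetic RNA-seq study used to exercise the pipeline
#' end to end with known ground truth. The defaults emulate the study
#' design the pipeline targets: stranded 50 bp uniquely mapped reads, a mix
#' of unspliced and 2-block spliced alignments, annotated multi-exon genes,
#' planted unannotated multi-exon transcripts (the truth NTRs, >= 3 exons
#' so every truth model carries >= 2 junction sites), and junctionless
#' decoy spots that must land in the singleton/rejected bins. Intron
#' lengths are drawn uniformly with mean 3 kb, echoing the genome-wide mean
#' intron length of the target organism; models are separated by at least
#' `min_gene_gap` bp so that planted NTRs are farther than D1 from every
#' gene and farther than D2 from each other.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Annotated genes to place.
#' @param n_ntrs Planted unannotated transcripts.
#' @param ntr_exons,gene_exons Integer ranges (length-2) of exon counts.
#' @param exon_len,intron_len Uniform ranges (bp) for exon and intron
#'   lengths.
#' @param read_length Read length in bp (default 50).
#' @param depth Mean read coverage per transcribed base.
#' @param spliced_read_fraction Fraction of reads deliberately placed
#'   across a splice junction (uniform placement adds more by chance).
#' @param min_gene_gap Minimum gap between placed models in bp; must
#'   exceed the discovery D1 so planted NTRs are not excluded as gene
#'   extensions, and D2 so same-strand models never fuse (default 6000).
#' @param decoy_singletons Junctionless single-exon transcribed spots.
#' @param decoy_len Uniform range (bp) for decoy lengths.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 400000L,
                       n_genes = 20L, n_ntrs = 10L,
                       ntr_exons = c(3L, 4L), gene_exons = c(2L, 5L),
                       exon_len = c(150L, 400L),
                       intron_len = c(1500L, 4500L),
                       read_length = 50L, depth = 20,
                       spliced_read_fraction = 0.2,
                       min_gene_gap = 6000L, decoy_singletons = 5L,
                       decoy_len = c(100L, 300L)) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0, n_ntrs >= 0,
            length(ntr_exons) == 2, ntr_exons[1] >= 2,
            read_length >= 20, depth > 0,
            spliced_read_fraction >= 0, spliced_read_fraction <= 1,
            min_gene_gap >= 0, decoy_singletons >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a toy genome, annotation, and stranded reads with ground truth
#'
#' Places annotated genes, planted NTR models, and junctionless decoys on
#' the toy genome without same-strand conflicts, then samples reads
#' uniformly along each model's exonic sequence at the configured depth.
#' Reads crossing an exon boundary become spliced alignments with a
#' reference-skip gap. Every read is uniquely mapped by construction
#' (`NH:i:1`, MAPQ 50). Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.genes.gtf`, `<prefix>.reads.sam`, `<prefix>.truth.bed`
#'   (BED12 of planted NTR models) and `<prefix>.truth.json`.
#' @return An `ntr_sim` list: `config`, `genes`, `ntr_models`, `decoys`
#'   (annotation tibbles), `reads` (same shape as [read_alignments()]
#'   output), `provenance` (read_id -> source model), `chrom_lengths`.
#' @export
simulate_reads <- function(config = sim_config(), out_prefix = NULL) {
  sim <- with_seed(config$seed, simulate_impl(config))
  if (!is.null(out_prefix)) {
    write_gtf(sim$genes, paste0(out_prefix, ".genes.gtf"))
    write_sam(sim$reads, sim$chrom_lengths, paste0(out_prefix, ".reads.sam"))
    truth <- sim$ntr_models |>
      mutate(ntr_id = .data$transcript_id,
             n_junctions = .data$n_exons - 1L,
             cov_starts = .data$exon_starts, cov_ends = .data$exon_ends)
    write_ntr_bed(truth, paste0(out_prefix, ".truth.bed"))
    jsonlite::write_json(
      list(seed = config$seed,
           genes = sim$genes$transcript_id,
           ntr_models = sim$ntr_models[c("transcript_id", "chrom", "start",
                                         "end", "strand")],
           decoys = sim$decoys[c("transcript_id", "chrom", "start", "end",
                                 "strand")],
           n_reads = nrow(sim$reads)),
      paste0(out_prefix, ".truth.json"), auto_unbox = TRUE)
  }
  sim
}

# Run `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

simulate_impl <- function(config) {
  models <- place_models(config)
  reads_list <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    reads_list[[i]] <- sample_model_reads(models[i, ], config)
  }
  reads <- list_rbind(reads_list)
  reads <- arrange(reads, natural_chrom_order(.data$chrom), .data$start,
                   .data$end, .data$read_id)
  provenance <- tibble(
    read_id = reads$read_id,
    source_id = sub(":[0-9]+$", "", reads$read_id)
  ) |>
    left_join(models[c("transcript_id", "model_type")],
              by = c(source_id = "transcript_id"))
  ann_cols <- c("transcript_id", "gene_id", "chrom", "start", "end",
                "strand", "n_exons", "exon_starts", "exon_ends")
  structure(
    list(config = config,
         genes = models[models$model_type == "gene", ann_cols],
         ntr_models = models[models$model_type == "ntr", ann_cols],
         decoys = models[models$model_type == "decoy", ann_cols],
         reads = reads,
         provenance = provenance,
         chrom_lengths = setNames(rep(config$chrom_length,
                                      config$n_chromosomes),
                                  paste0("chr", seq_len(config$n_chromosomes)))),
    class = "ntr_sim"
  )
}

# Lay models down chromosome by chromosome with random gaps >= min_gene_gap.
place_models <- function(config) {
  types <- c(rep("gene", config$n_genes), rep("ntr", config$n_ntrs),
             rep("decoy", config$decoy_singletons))
  if (length(types) == 0L) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_exons = integer(),
                  exon_starts = list(), exon_ends = list(),
                  model_type = character()))
  }
  types <- sample(types)
  counters <- c(gene = 0L, ntr = 0L, decoy = 0L)
  rows <- list()
  chrom_i <- 1L
  cursor <- 0L
  for (ty in types) {
    n_ex <- switch(ty,
      gene = sample(config$gene_exons[1]:config$gene_exons[2], 1),
      ntr = sample(config$ntr_exons[1]:config$ntr_exons[2], 1),
      decoy = 1L)
    ex_len <- if (ty == "decoy") {
      sample(config$decoy_len[1]:config$decoy_len[2], n_ex, replace = TRUE)
    } else {
      sample(config$exon_len[1]:config$exon_len[2], n_ex, replace = TRUE)
    }
    in_len <- if (n_ex > 1) {
      sample(config$intron_len[1]:config$intron_len[2], n_ex - 1,
             replace = TRUE)
    } else integer()
    gap <- sample(config$min_gene_gap:(2 * config$min_gene_gap), 1)
    span <- sum(ex_len) + sum(in_len)
    if (cursor + gap + span > config$chrom_length) {
      chrom_i <- chrom_i + 1L
      cursor <- 0L
      if (chrom_i > config$n_chromosomes) {
        abort(paste("genome too small for the requested models:",
                    "increase chrom_length or n_chromosomes,",
                    "or reduce model counts / min_gene_gap"))
      }
      if (gap + span > config$chrom_length) {
        abort("chrom_length too small for a single model plus gap")
      }
    }
    start <- cursor + gap
    offs <- cumsum(c(0L, head(ex_len + c(in_len, 0L), -1)))
    es <- as.integer(start + offs)
    ee <- as.integer(es + ex_len)
    counters[ty] <- counters[ty] + 1L
    id <- paste0(ty, counters[ty])
    rows[[length(rows) + 1L]] <- tibble(
      transcript_id = id, gene_id = id,
      chrom = paste0("chr", chrom_i),
      start = es[1], end = ee[n_ex],
      strand = sample(STRANDS, 1),
      n_exons = n_ex, exon_starts = list(es), exon_ends = list(ee),
      model_type = ty
    )
    cursor <- ee[n_ex]
  }
  list_rbind(rows)
}

# Sample reads uniformly along one model's exonic (spliced) sequence and
# project them back to genomic blocks.
sample_model_reads <- function(model, config) {
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  ex_len <- ee - es
  L <- sum(ex_len)
  rl <- min(config$read_length, L)
  n_reads <- max(1L, as.integer(ceiling(config$depth * L / rl)))
  max_t <- L - rl
  t0 <- sample.int(max_t + 1L, n_reads, replace = TRUE) - 1L
  # force a fraction of reads across a junction (multi-exon models only)
  if (length(es) > 1L && config$spliced_read_fraction > 0 && max_t > 0) {
    n_spliced <- as.integer(round(config$spliced_read_fraction * n_reads))
    if (n_spliced > 0) {
      bounds <- cumsum(ex_len)[-length(ex_len)]  # transcript coords of junctions
      j <- bounds[sample.int(length(bounds), n_spliced, replace = TRUE)]
      off <- sample.int(rl - 1L, n_spliced, replace = TRUE)
      forced <- pmax(0L, pmin(max_t, j - off))
      t0[seq_len(n_spliced)] <- forced
    }
  }
  cum <- cumsum(c(0L, ex_len))
  blocks <- map(t0, function(t) project_to_genome(t, rl, es, ee, cum))
  tibble(
    read_id = paste0(model$transcript_id, ":", seq_len(n_reads)),
    chrom = model$chrom,
    start = map_int(blocks, function(b) b$start[1]),
    end = map_int(blocks, function(b) b$end[length(b$end)]),
    strand = model$strand,
    mapq = 50L,
    n_blocks = map_int(blocks, function(b) length(b$start)),
    block_starts = map(blocks, "start"),
    block_ends = map(blocks, "end")
  )
}

# Project transcript-coordinate interval [t, t + rl) onto genomic blocks.
project_to_genome <- function(t, rl, es, ee, cum) {
  remaining <- rl
  pos <- t
  bs <- integer(); be <- integer()
  while (remaining > 0L) {
    ex <- findInterval(pos, cum, rightmost.closed = FALSE)
    within <- pos - cum[ex]
    take <- min(remaining, (ee[ex] - es[ex]) - within)
    g0 <- es[ex] + within
    bs <- c(bs, as.integer(g0)); be <- c(be, as.integer(g0 + take))
    remaining <- remaining - take
    pos <- pos + take
  }
  list(start = bs, end = be)
}

#' Write reads as a SAM file
#'
#' Minimal coordinate-sorted SAM serialisation of a read tibble: FLAG 0/16
#' from the strand, MAPQ, CIGAR rebuilt from the aligned blocks
#' (match/reference-skip only), `NH:i:1`. Reads back through
#' [read_alignments()].
#'
#' @param reads Read tibble.
#' @param chrom_lengths Named vector of chromosome lengths for `@SQ` lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  reads <- arrange(reads, natural_chrom_order(.data$chrom), .data$start,
                   .data$end, .data$read_id)
  cigar <- pmap(list(reads$block_starts, reads$block_ends),
                function(bs, be) {
      m <- be - bs
      if (length(bs) == 1L) return(sprintf("%dM", m))
      gaps <- bs[-1] - be[-length(be)]
      paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
             m[length(m)], "M")
    })
  seq <- map_chr(map2(reads$block_starts, reads$block_ends,
                      function(bs, be) sum(be - bs)),
                 function(n) strrep("A", n))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:1",
                  reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                  reads$chrom, reads$start + 1L, reads$mapq,
                  unlist(cigar), seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Compare NTR calls against planted truth models
#'
#' Greedy one-to-one matching by descending reciprocal overlap on the same
#' strand: a call matches a truth model when each covers at least
#' `min_reciprocal_overlap` of the other (span overlap). Precision is
#' matched calls over all calls (`NA` when there are no calls), recall is
#' matched truth models over all truth models.
#'
#' @param calls NTR call tibble (from [run_discovery()] / [tidy()]).
#' @param truth Truth model tibble (`transcript_id` or `ntr_id`, `chrom`,
#'   `start`, `end`, `strand`), e.g. `ntr_models` from [simulate_reads()].
#' @param min_reciprocal_overlap Matching threshold in (0, 1] (default
#'   0.5).
#' @return A list with `precision`, `recall`, `n_matched`, and `matches`
#'   (tibble of matched call/truth ids with their reciprocal overlap).
#' @export
evaluate_calls <- function(calls, truth, min_reciprocal_overlap = 0.5) {
  truth_id <- truth$transcript_id %||% truth$ntr_id
  empty <- tibble(call_id = character(), truth_id = character(),
                  reciprocal_overlap = numeric())
  if (nrow(calls) == 0L || nrow(truth) == 0L) {
    return(list(
      precision = if (nrow(calls) == 0L) NA_real_ else 0,
      recall = if (nrow(truth) == 0L) NA_real_ else 0,
      n_matched = 0L, matches = empty))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(calls), intervals_to_granges(truth),
    minoverlap = 1L, ignore.strand = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls$end[qi], truth$end[si]) -
    pmax(calls$start[qi], truth$start[si])
  ro <- pmin(ov / (calls$end[qi] - calls$start[qi]),
             ov / (truth$end[si] - truth$start[si]))
  cand <- tibble(call = qi, truth = si, ro = ro) |>
    filter(.data$ro >= min_reciprocal_overlap) |>
    arrange(desc(.data$ro), .data$call, .data$truth)
  used_call <- logical(nrow(calls)); used_truth <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ci <- cand$call[k]; ti <- cand$truth[k]
    if (!used_call[ci] && !used_truth[ti]) {
      keep[k] <- TRUE
      used_call[ci] <- TRUE
      used_truth[ti] <- TRUE
    }
  }
  matched <- cand[keep, ]
  list(
    precision = nrow(matched) / nrow(calls),
    recall = nrow(matched) / nrow(truth),
    n_matched = nrow(matched),
    matches = tibble(call_id = calls$ntr_id[matched$call],
                     truth_id = truth_id[matched$truth],
                     reciprocal_overlap = matched$ro)
  )
}
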