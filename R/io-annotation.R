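#' Read a transcript annotation from GTF
#'
#' Imports the exon features of a GTF file (1-based inclusive per the GTF
#' standard) and assembles one row per transcript with its exon structure,
#' converted to the internal 0-based half-open convention. The transcript
#' interval is the hull of its exons.
#'
#' @param path Path to a GTF file. An empty file yields an empty (valid)
#'   annotation.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_exons`, and list-columns
#'   `exon_starts`/`exon_ends` (sorted, non-overlapping).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  empty <- tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    n_exons = integer(), exon_starts = list(), exon_ends = list()
  )
  if (file.size(path) == 0L) return(empty)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(empty)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    abort("GTF exon feature without transcript_id attribute")
  }
  gene_id <- if (is.null(gr$gene_id)) gr$transcript_id else
    coalesce(gr$gene_id, gr$transcript_id)
  exons <- tibble(
    transcript_id = gr$transcript_id,
    gene_id = gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  check_strand(exons$strand, "GTF exon")
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      n_exons = n(),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      start = min(.data$start),
      end = max(.data$end),
      .by = "transcript_id"
    ) |>
    relocate("transcript_id", "gene_id", "chrom", "start", "end", "strand") |>
    arrange(natural_chrom_order(.data$chrom), .data$start)
}

#' Write a transcript annotation as GTF
#'
#' Serialises an annotation tibble (see [read_annotation()]) back to GTF:
#' one `transcript` feature plus one `exon` feature per exon, 1-based
#' inclusive coordinates. Round-trips through [read_annotation()].
#'
#' @param annotation Annotation tibble.
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source = "ntrscout") {
  lines <- pmap(
    list(annotation$chrom, annotation$start, annotation$end,
         annotation$strand, annotation$gene_id, annotation$transcript_id,
         annotation$exon_starts, annotation$exon_ends),
    function(chrom, start, end, strand, gid, tid, es, ee) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      c(
        paste(chrom, source, "transcript", start + 1L, end, ".", strand, ".",
              attrs, sep = "\t"),
        paste(chrom, source, "exon", es + 1L, ee, ".", strand, ".", attrs,
              sep = "\t")
      )
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

# GRanges view of transcript spans, for overlap/nearest queries.
annotation_granges <- function(annotation) {
  intervals_to_granges(annotation)
}
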