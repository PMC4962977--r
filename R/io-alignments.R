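#' Read uniquely mapped spliced alignments from SAM/BAM
#'
#' Streams a coordinate-sortable SAM or BAM file into a tibble of aligned
#' reads, one row per read, keeping only primary mapped records that pass the
#' uniqueness policy. Aligned segments (blocks) are derived from the CIGAR:
#' reference skips (`N`, introns) split blocks, while insertions and
#' deletions stay inside a block, following standard spliced-alignment
#' semantics. All coordinates are 0-based half-open.
#'
#' The uniqueness policy mirrors common aligner conventions: a read is
#' accepted iff its `NH` tag equals 1 when the tag is present, otherwise iff
#' its MAPQ is at least `mapq_min`. Both knobs are exposed because
#' "uniquely mapped" is aligner-specific.
#'
#' @param path Path to a SAM or BAM file.
#' @param mapq_min Minimum MAPQ accepted when no `NH` tag is present
#'   (default 20). Records with missing MAPQ (255) are rejected under the
#'   MAPQ fallback.
#' @param use_nh Consult the `NH` tag when present (default `TRUE`).
#' @param strand_from `"flag"` (default) takes the read strand from the
#'   reverse-complement FLAG bit; `"tag"` prefers a transcription-strand tag
#'   (`strand_tag`, default `XS`) when present, falling back to the flag.
#' @param strand_tag Tag consulted when `strand_from = "tag"`.
#' @param skip_duplicates Drop records flagged as PCR/optical duplicates
#'   (default `FALSE`: no deduplication).
#' @return A tibble with one row per accepted read: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `mapq`, `n_blocks`, and list-columns
#'   `block_starts`/`block_ends` holding the aligned segments. Rows are
#'   sorted by (`chrom`, `start`).
#' @export
read_alignments <- function(path, mapq_min = 20L, use_nh = TRUE,
                            strand_from = c("flag", "tag"),
                            strand_tag = "XS",
                            skip_duplicates = FALSE) {
  strand_from <- match.arg(strand_from)
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bam <- as_bam(path)

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (skip_duplicates) FALSE else NA
  )
  tags <- unique(c("NH", if (strand_from == "tag") strand_tag))
  param <- Rsamtools::ScanBamParam(flag = flag, tag = tags,
                                   what = c("qname", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)

  mcols <- S4Vectors::mcols(ga)
  nh <- mcols$NH
  mapq <- mcols$mapq
  mapq[is.na(mapq)] <- 255L
  keep <- if (use_nh && !is.null(nh)) {
    ifelse(!is.na(nh), nh == 1L, mapq != 255L & mapq >= mapq_min)
  } else {
    mapq != 255L & mapq >= mapq_min
  }
  ga <- ga[keep]
  mcols <- S4Vectors::mcols(ga)

  strand <- as.character(BiocGenerics::strand(ga))
  if (strand_from == "tag") {
    tag_strand <- mcols[[strand_tag]]
    if (!is.null(tag_strand)) {
      use_tag <- !is.na(tag_strand) & tag_strand %in% STRANDS
      strand[use_tag] <- tag_strand[use_tag]
    }
  }
  if (any(!strand %in% STRANDS)) {
    abort("alignment with undetermined strand (unstranded '*' record)")
  }

  bl <- GenomicAlignments::grglist(ga)
  block_starts <- as.list(BiocGenerics::start(bl) - 1L)
  block_ends <- as.list(BiocGenerics::end(bl))

  out <- tibble(
    read_id = as.character(mcols$qname),
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    start = BiocGenerics::start(ga) - 1L,
    end = BiocGenerics::end(ga),
    strand = strand,
    mapq = as.integer(mcols$mapq),
    n_blocks = lengths(block_starts),
    block_starts = block_starts,
    block_ends = block_ends
  )
  arrange(out, natural_chrom_order(.data$chrom), .data$start, .data$end)
}

# SAM input is converted (and coordinate-sorted) through a temporary BAM so
# one reader handles both formats.
as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
}

#' Extract splice junctions from aligned reads
#'
#' A splice junction is the intron implied by a reference skip between two
#' consecutive aligned blocks of one read; its identity is the tuple
#' (`chrom`, `intron_start`, `intron_end`, `strand`). Multiple reads spanning
#' the same intron count as one junction site; their number is retained as
#' `support`.
#'
#' @param reads A read tibble from [read_alignments()].
#' @return A tibble with `chrom`, `intron_start`, `intron_end` (0-based
#'   half-open), `strand`, and `support` (number of reads spanning the
#'   junction), sorted by position.
#' @export
extract_junctions <- function(reads) {
  spliced <- reads[reads$n_blocks > 1L, ]
  if (nrow(spliced) == 0L) {
    return(tibble(chrom = character(), intron_start = integer(),
                  intron_end = integer(), strand = character(),
                  support = integer()))
  }
  per_read <- pmap(
    list(spliced$chrom, spliced$strand, spliced$block_starts, spliced$block_ends),
    function(chrom, strand, bs, be) {
      n <- length(bs)
      tibble(chrom = chrom, intron_start = be[-n], intron_end = bs[-1],
             strand = strand)
    }
  )
  list_rbind(per_read) |>
    count(.data$chrom, .data$intron_start, .data$intron_end, .data$strand,
          name = "support") |>
    arrange(natural_chrom_order(.data$chrom), .data$intron_start,
            .data$intron_end)
}
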