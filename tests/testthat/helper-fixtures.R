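# Fixture builders: all reads/annotations are constructed in code, and SAM /
# GTF files are written to tempdir() at test time.

# One read row; `blocks` is an optional list(starts =, ends =) for spliced
# reads, otherwise the read is a single block over [start, end).
make_read <- function(chrom, start, end, strand = "+", id = NULL,
                      blocks = NULL, mapq = 50L) {
  bs <- if (is.null(blocks)) as.integer(start) else as.integer(blocks$starts)
  be <- if (is.null(blocks)) as.integer(end) else as.integer(blocks$ends)
  tibble::tibble(
    read_id = id %||% paste0("r", start, "_", sample.int(1e6, 1)),
    chrom = chrom, start = as.integer(bs[1]), end = as.integer(be[length(be)]),
    strand = strand, mapq = as.integer(mapq),
    n_blocks = length(bs), block_starts = list(bs), block_ends = list(be)
  )
}

make_reads <- function(...) dplyr::bind_rows(...)

# Random reads over a small genome; a fraction spliced with one intron.
random_reads <- function(n, chroms = c("chr1", "chr2"), span = 20000L,
                         read_len = 50L, spliced_frac = 0.3,
                         intron_range = c(60L, 2000L)) {
  purrr::map(seq_len(n), function(i) {
    chrom <- sample(chroms, 1)
    strand <- sample(c("+", "-"), 1)
    s <- sample.int(span, 1)
    if (stats::runif(1) < spliced_frac) {
      b1 <- sample.int(read_len - 20L, 1) + 9L
      intron <- sample(intron_range[1]:intron_range[2], 1)
      make_read(chrom, s, NULL, strand, id = paste0("r", i),
                blocks = list(starts = c(s, s + b1 + intron),
                              ends = c(s + b1, s + intron + read_len)))
    } else {
      make_read(chrom, s, s + read_len, strand, id = paste0("r", i))
    }
  }) |> purrr::list_rbind()
}

# Minimal annotation row (single- or multi-exon transcript).
make_transcript <- function(id, chrom, start, end, strand = "+",
                            exon_starts = NULL, exon_ends = NULL,
                            gene_id = id) {
  es <- if (is.null(exon_starts)) as.integer(start) else as.integer(exon_starts)
  ee <- if (is.null(exon_ends)) as.integer(end) else as.integer(exon_ends)
  tibble::tibble(
    transcript_id = id, gene_id = gene_id, chrom = chrom,
    start = as.integer(es[1]), end = as.integer(ee[length(ee)]),
    strand = strand, n_exons = length(es),
    exon_starts = list(es), exon_ends = list(ee)
  )
}

write_sam_fixture <- function(lines, chroms = c(chr1 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, lines), path)
  path
}

sam_line <- function(qname, flag, chrom, pos1, mapq, cigar, tags = "NH:i:1") {
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", "0", "0", "*", "*", tags,
        sep = "\t")
}
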