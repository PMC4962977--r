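Package: ntrscout
Title: Discovery and Expression Profiling of Novel Transcribed Regions
    from RNA-Seq Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-guided discovery of novel transcribed regions (NTRs)
    from uniquely mapped, stranded RNA-seq alignments. Reads are merged
    into fragments (maximal same-strand groups overlapping by at least one
    base pair, or single spliced reads), fragments near annotated
    transcripts are excluded (distance D1), the remainder are chained into
    clusters (linkage distance D2), and clusters are filtered by splice
    junction support before subtraction of secondary annotation releases.
    Includes FPKM quantification of calls across developmental stages with
    fold change against a baseline stage, per-stage sequencing run
    summaries, a seeded read simulator with planted ground-truth
    transcripts for end-to-end evaluation, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
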