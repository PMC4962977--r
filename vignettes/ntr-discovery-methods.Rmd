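---
title: "Methods: fragment-and-cluster discovery of novel transcribed regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-and-cluster discovery of novel transcribed regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntrscout)
```

## The problem

Genome annotations of model organisms such as zebrafish are incomplete:
bulk RNA-seq of early developmental stages routinely shows transcription
from loci absent from the reference gene set. `ntrscout` implements a
genome-guided procedure for calling such *novel transcribed regions*
(NTRs) from stranded, uniquely mapped spliced alignments, without
attempting transcript assembly. The unit of evidence is deliberately
coarse — contiguous patches of reads — and specificity comes from three
filters: distance from annotated genes, splice-junction support, and
subtraction of newer annotation releases.

## The model

**Reads.** Only uniquely mapped primary alignments enter the analysis.
"Unique" is aligner-specific, so the reader accepts a record iff its `NH`
tag equals 1 when the tag is present, falling back to a MAPQ threshold
(default 20) otherwise; both knobs are exposed. Aligned blocks are taken
from the CIGAR: reference skips (`N`) split blocks and imply splice
junctions, while insertions and deletions stay inside a block. No
duplicate removal is performed by default (flagged duplicates can be
dropped via a switch); the procedure counts reads, and deduplication
policy is left to upstream processing.

**Fragments.** A *fragment* is a maximal set of same-strand reads in
which adjacent reads overlap by at least one base pair at their ends; a
single spliced read forms a fragment on its own. Two consequences are
worth stating precisely:

* *Bookended reads do not merge.* Overlap must be ≥ 1 bp, so reads
  meeting end-to-start stay in separate fragments. Coverage blocks, in
  contrast, are merged bookended-inclusively, because they model
  transcribed bases rather than read connectivity.
* *Connectivity uses the read span.* A spliced read spans its intron, so
  a read falling entirely inside that intron joins the same fragment.
  Whether the original formulation connected spliced reads to their
  neighbours through spans or through exonic blocks is not decidable from
  its description; the span rule is the package default and a
  `connect = "blocks"` mode implements the alternative.

Each fragment carries the union of its reads' junction sites — a junction
site is the tuple (chromosome, intron start, intron end, strand), counted
once however many reads support it, with the support count retained — and
the merged coverage of its reads' blocks.

**D1 — annotation exclusion.** Fragments lying at distance ≤ D1 (default
1000 bp) from any annotated transcript on the same strand, at either end,
are excluded: they could be unannotated extensions of known genes.
Distance is the half-open gap (`next start − previous end`); overlap means
distance 0. The boundary is inclusive — a gap of exactly D1 is excluded —
which follows directly from the operational phrasing of the source method
("1 kb or less away"). Exclusion is same-strand by default because the
stated rule is strand-specific; a flag allows strand-agnostic exclusion
since the treatment of antisense overlap was never stated. Enlarging D1
can only shrink the kept set (a monotonicity the tests assert).

**D2 — clustering.** Remaining same-strand fragments whose gap is ≤ D2
(default 5000 bp) chain into *clusters*; a cluster is a connected chain,
computed by a single sweep over start-sorted fragments. The source
method's prose uses both "less than D2" and "less or equal to 5 kb"; the
inclusive rule is adopted because the operational description uses ≤, and
`strict_d2 = TRUE` switches to the strict form. Enlarging D2 can only
reduce the number of clusters.

**Junction and singleton filters.** A cluster is a candidate NTR only if
it contains at least two distinct splice-junction sites (`min_junctions`,
default 2) — junctionless or single-junction clusters are too easily
produced by mapping noise. Distinct *sites* are counted, not supporting
reads; clusters whose ≥ 2 junctions all come from one read still pass, as
nothing in the source formulation says otherwise. A minimum read support
per junction site is available (`min_junction_support`, default 1).
Junctionless one-fragment clusters longer than 50 bp are reported as
*singletons* — plausible candidates for short noncoding transcripts, never
called. The 50 bp rule is strict ("length over 50 bp").

**Secondary subtraction.** Candidates overlapping (≥ 1 bp, same strand)
any transcript of one or more *secondary* annotations — e.g. newer
annotation releases — are removed. This is an overlap test, not a D1
proximity test, because the secondary check asks "has this been annotated
since?", an identity notion. Survivors are the NTR calls, numbered in
genomic order (natural chromosome order, then start). A call's reported
span is the hull of its read coverage, and its exonic length — used as
the FPKM length term — is the sum of its merged coverage blocks.

Every run returns a count ledger (total fragments, in-annotation,
proximal, clustered, clusters, junction-rejected, singletons,
secondary-removed, final calls) whose conservation identity
`total = in_annotation + proximal + clustered` holds on all inputs,
including empty ones.

## Expression profiling

Reads are assigned to a call by ≥ 1 bp same-strand span overlap (block
overlap is available as an option), and expression is

FPKM = count / ((exonic length / 10³) × (library size / 10⁶)).

This is the plain definition, used deliberately instead of a
model-based estimator: the original study quantified with Cuffdiff, whose
internal normalisation is not reproducible from its outputs, and the
package makes no claim of numeric parity with it. Fold changes divide
each stage column by a baseline stage (the 1-cell stage in the intended
design); rows with baseline 0 are *flagged undefined* rather than mapped
to infinity, mirroring the real case of an NTR first expressed after the
baseline stage. For profile-shape comparison, rows can be standardised to
mean 0 and unit standard deviation (sample sd, n−1, switchable); constant
rows map to zeros.

Four-stage profiles are classified with a deterministic priority rule:
`post_mbt_up` (final stage above the third), `mbt_peak` (third stage the
strict maximum), `maternal_decay` (first stage the strict maximum,
non-increasing within a 10 % relative tolerance), `low_flat` (all below
1 FPKM with relative range within tolerance), else `other`. The threshold
and tolerance are package choices — the patterns in the source study are
qualitative — and both are arguments.

## The simulator and what passing tests mean

The simulator emulates the study design the pipeline targets: stranded
50 bp uniquely mapped reads over a toy genome with annotated multi-exon
genes, planted unannotated transcripts (≥ 3 exons, hence ≥ 2 junction
sites), and junctionless decoy spots that must end in the singleton or
rejected bins. Defaults: 2 chromosomes × 400 kb, 20 genes, 10 planted
NTRs, 5 decoys, exons 150–400 bp, introns uniform 1.5–4.5 kb (mean 3 kb,
echoing the genome-wide mean intron length in zebrafish), depth 20 reads
per transcribed base, and a minimum inter-model gap of 6 kb — above both
D1 (so planted NTRs are not excluded as gene extensions) and D2 (so
distinct models never fuse). Reads are sampled uniformly along each
model's exonic sequence, with a configurable fraction forced across a
junction; reads crossing an exon boundary are emitted as spliced
alignments. All randomness flows from one seed, and outputs are
byte-identical given the seed.

Calls are scored against the planted truth by greedy one-to-one matching
on descending reciprocal span overlap (threshold 0.5, same strand);
precision is matched/calls and recall matched/truth. At the default
settings the pipeline recovers essentially all planted models over many
seeds.

What this does *not* show: the simulator has no sequencing error, no
multi-mapping ambiguity (uniqueness holds by construction), no coverage
dips inside transcripts, no antisense transcription, and no expression
differences across models. Passing its tests demonstrates the
correctness of the interval algebra, the filters, and the ledger — not
the biological error rate on real libraries, which depends on mapping
quality and library strandedness. The genome-scale counts of the original
study are likewise out of reach by design: they require the original
SOLiD colour-space data and a deprecated aligner toolchain, so the test
suite checks the *direction* of parameter effects (e.g. fewer clusters at
D2 = 10 kb than at 5 kb) rather than their absolute values.

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  inclusive) and the per-call report table (1-based inclusive) are
  converted only at the format boundary; BED is native 0-based half-open.
* Sequencing-summary tables round half-up at one decimal
  (`total_reads()`, `mapped_pct()`), matching tabular presentation;
  base R's round-half-even is not used there.
* Fragment distance classification uses the distance value alone:
  distance 0 covers both true overlap and the measure-zero bookended
  case, which is therefore binned with "in annotation".
* Chromosome order for call numbering is a natural sort (chr2 before
  chr10), then start coordinate.
* Degenerate inputs: empty alignment or annotation files are valid and
  yield empty tibbles and an all-zero ledger; zero-length intervals,
  unknown strands, exons without `transcript_id`, and zero FPKM
  denominators are hard errors.
* Problem sizes in the shipped tests are the simulator defaults above;
  oracle-equivalence checks run against brute-force pairwise-graph and
  bitmap implementations on instances of up to 200 reads, and recovery is
  pooled over 20 seeded replicates.

## Known limitations

The caller reports transcribed regions, not transcript models: isoform
structure within a cluster is out of scope. Boundary precision is
coverage-limited — spans extend only as far as reads reach. Antisense
transcription inside annotated genes is kept by design (same-strand
exclusion), which may surface antisense RNAs but also strand-mapping
artefacts on poorly stranded libraries. FPKM values are comparable within
a run but are not Cuffdiff-compatible.
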