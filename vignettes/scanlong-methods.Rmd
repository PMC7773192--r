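---
title: "Methods: long-read single-cell full-length transcriptome analysis"
author: "scanlong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read single-cell full-length transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
conventions behind `scanlong`, and what its simulation-based tests do and
do not establish about real data.

## Coordinates and data containers

All genomic coordinates are 0-based half-open internally; conversion
happens only at format boundaries (GTF and VCF are 1-based, BAM blocks are
converted on load). A junction is keyed `(chrom, strand, donor, acceptor)`
with `donor < acceptor` in genomic coordinates regardless of strand —
strand only affects the biological labeling — so a splice event has
exactly one key. For an exon `[s, e)` followed by `[s', e')`, the junction
is `(e, s')` and the intron is `[e, s')`. The annotation index
pre-computes per-transcript junction chains, per-(chrom, strand) splice
edge sets, junction ownership, and exon/gene interval trees (GenomicRanges).
Secondary and supplementary alignments are flagged and excluded from
quantification by default, matching a single-best-alignment mapping
configuration.

## Barcode demultiplexing

Each read contributes its first and last `min(150, length)` bases as
windows (reads shorter than the window use the whole read for both, so
short-but-valid reads are not lost before the length filter). Every
barcode is scored against both windows on both strands with a semi-global
affine alignment: the barcode aligned end to end, window overhangs free;
match +2, mismatch −2, gap open −3, gap extend −1 (a gap of length *k*
costs `3 + (k−1)`). Because the published demultiplexer does not document
its score matrix, this scheme was chosen so that the assignment cutoff of
31 keeps its published semantics: a perfect 24-mer scores 48, each
substitution costs 4, so 31 tolerates about four substitutions
(20·2 − 4·2 = 32 ≥ 31; five substitutions give 28 < 31). The cutoff is a
strict lower bound — a best score of exactly 31 is assigned. Ties at the
maximum are left unassigned rather than arbitrarily broken, trading a
small loss of yield against cell cross-talk. Scoring is strand-symmetric
(`score(b, rc(w)) = score(rc(b), w)`), so both window strands are covered
by scoring each barcode and its reverse complement. The inner dynamic
program runs over all barcodes simultaneously in compiled code (Rcpp,
int16 cells) so a 10,000-read × 48-barcode library demultiplexes in
seconds.

Simulated barcode sets are required to have pairwise edit distance ≥ 8 at
design load; commercial barcode sets are separated comparably, and this
guarantees the score-separation the accuracy tests rely on.

## Read architecture, orientation, trimming

The sense amplicon is `anchor + ATGGG + transcript + polyA +
rc(barcode) + rc(anchor)`, with the 25-nt ISPCR anchor shared by the TSO
and RT primers. Anchor occurrences are located by alignment with at most
5 edits. The RT end is recognized by a polyT (or polyA, depending on
orientation) signal near the barcode: any 15-base window with ≥ 75%
T (A) content within 10 bases of the expected barcode position. Detection
is deliberately content-based rather than exact-run-based because at a
~9% combined error rate a pure 15-mer run inside a 25-base tail is
frequently interrupted; trimming, by contrast, cuts at the start of the
longest *pure* A-run (≥ 8) before the barcode so that error-free reads are
trimmed exactly, at the cost of occasional tail remnants on noisy reads.
The `ATGGG` TSO tail is treated as optional evidence (trimmed when present
within one edit) — full-length status requires the anchor at both ends
plus the RT signal, not the tail. Reads with anchor hits away from both
ends are chimeric (concatemers) and are reported and excluded, not split;
splitting is a rescue heuristic we do not attempt. The transcribed strand
of the molecule is "+" when no reverse complement was needed to put the
TSO end 5′, "−" otherwise.

A genuine ambiguity is inherited from the chemistry: a genomically encoded
3′ adenosine stretch cannot be distinguished from the oligo-dT tail. The
simulator therefore forces the last transcript base to a non-A (and keeps
SNPs off that base) so that exact-trim tests are well defined; real 3′
ends that terminate in long A-runs will be trimmed conservatively.

The read-level filters (mean qscore ≥ 7, length ≥ 100) and the cell-level
filters (≥ 100,000 full-length reads, base mapping ratio ≥ 0.85, ≥ 3,000
detected genes) all follow the strict "less than" exclusion reading:
equality passes. The qscore is the Phred of the mean per-base error
probability, `−10·log10(mean(10^(−q/10)))`, the standard long-read
convention; the alternative (mean of Phreds) differs and was deliberately
not used.

## Quantification

Transcript assignment is junction-chain compatibility: candidates are
same-strand transcripts whose chain contains the read's chain as a
contiguous subchain (each edge within ±5 bp, absorbing splice-edge wobble)
and whose span covers the read. One read distributes weight 1 equally
among its candidates; mono-exon reads inside an exon shared by *n*
transcripts contribute 1/*n* to each. This replaces an external
equivalence-class quantifier with a transparent rule that is exact on
full-length reads: on an error-free simulation gene-level counts equal the
truth exactly, and total weight is conserved under transcript-level
ambiguity. RPG10k/RPT10k normalize to 10,000 per cell with the summed
assignment weight as the mapped total, so the per-cell column sum is
10,000 by construction — tested to 1e-6. "Detected gene" means raw count
> 0; no expression floor is applied for detection since none is defined
for it. Cells with zero mapped reads are omitted with a warning.

Region classification has precedence exon > intron > intergenic over a
read's blocks, one label per read. Only intergenic reads enter lncRNA
quantification, which reuses the same assignment and normalization rules
against a secondary annotation, normalized within the lncRNA compartment.
Saturation curves subsample assigned reads without replacement (default
10 draws per depth, seeded) and report mean detected genes/transcripts.

## Novel isoform discovery

Per cell: (1) *cluster* — junction edges snap to the nearest annotated
splice edge within ±5 bp; chains equal after snapping (unannotated edges
compared within the same tolerance and rounded to the cluster median)
form a cluster; mono-exon reads cluster by ≥ 50% reciprocal overlap.
(2) *depth filter* — ≥ 2 reads when every splice edge is annotated and the
model lies within annotated exons; ≥ 5 reads when any edge is unannotated
or any exonic stretch (retained intron, novel exon, intergenic model) is
uncovered by annotated exons. (3) *collapse* — identical chains merge;
a chain that is a 5′-truncated contiguous fragment of a longer model's
chain sharing its 3′ end (genomic suffix on "+", genomic prefix on "−")
merges into the longer model; terminal exon ends are medians of the
supporting reads. (4) *classify* (below). Novel models are merged across
cells by chain identity (mono-exon: reciprocal overlap), added to the
annotation as transcripts of their host gene, and the whole read set is
re-quantified jointly so that expression filters see RPT10k computed over
known + novel transcripts together.

The classifier's decision tree, in order:

* multi-exon — exact chain match → **known**; a complete annotated intron
  of the host gene strictly inside a model exon (≥ 1 flanking exonic base
  on each side) → **IR**; contiguous subchain of an annotated chain →
  **known** (5′ truncation is degradation, not discovery); all junctions
  annotated in the host gene → **CJ**; all donor and acceptor edges
  annotated in the host gene with ≥ 1 novel pairing → **CS**; otherwise
  **discarded**.
* mono-exon — inside one annotated exon → **ME**; containing a complete
  annotated intron with both flanking exon edges → **MIR**; no gene
  overlap → **intergenic**; otherwise **discarded**.

Three genuinely open points were settled as follows. IR precedes the
subchain-known rule because a fused exon across an intron also shortens
the chain — intron retention is the more specific structural reading and
matches how retention events present in practice. Truncated subchains are
*known*, not novel, to avoid counting 5′ degradation as discovery.
Models with any unannotated splice edge after snapping are discarded
rather than given a sixth category: with raw long-read splice-edge error
they would otherwise dominate the novel set, and the category system is
deliberately closed at five. The junction-level reading of CJ versus CS
is used (CJ recombines whole annotated junctions; CS recombines annotated
edges into novel junctions). The 5% host-gene share is evaluated per cell,
the same scope as the RPT10k ≥ 0.1 floor; a novel transcript is retained
when both hold in ≥ 3 cells (boundaries inclusive).

The classifier is verified two ways: six hand-constructed worked examples,
and 1,000 seeded random toy annotations on which an independent
brute-force transcription of the category definitions (naive loops over
the raw exon table) must agree exactly. Planted-isoform recovery generates
one unannotated isoform per category from a purpose-built layout
(`make_planted_reference()`: a five-exon gene with two skip isoforms hosts
the CJ; three-exon genes host CS/ME/IR/MIR; a sixth gene absent from the
primary annotation serves as a planted lncRNA) and requires the full
cluster → filter → collapse → classify → merge → expression-filter chain
to return each with its true category.

## Allele-specific expression

The alternate genome applies biallelic substitutions only, so coordinates
remain directly comparable; ref-allele mismatches abort with the position.
A read participates when it covers ≥ 60% (inclusive) of its gene's
shortest annotated transcript — "shortest" is the minimum spliced length
over the gene's transcripts, and coverage is the read's aligned bases
overlapping the gene span divided by that length, capped at 1. The
per-gene minimum was chosen over "shortest compatible transcript" as the
plainer reading; the alternative is noted here for future work. At every
SNP under the read's blocks the read base is compared with both alleles;
third bases (sequencing errors) count for neither. Assignment: a single
informative SNP decides; otherwise a strain needs at least twice the
other's support (and ≥ 1 SNP); `(0,0)` is unassigned. The rule table is
tested exhaustively against a literal transcription over all support
pairs in `[0,10]²`.

Because mapping to either parental genome alone biases toward that
genome's alleles, calls are made under both references and the per-
cell×gene maternal/paternal *counts* are averaged (fractions recomputed
from averaged counts — averaging at count level rather than fraction
level weights cells' genes by evidence; the alternative is a one-line
change). The averaging operator is symmetric and idempotent by
construction and tested as such. Error rates come from known pure-strain
cells as wrongly assigned / all assigned informative reads, per strain.
SNP comparison uses the read base after alignment to each reference
independently, with no base-quality weighting — quality weighting is an
enhancement the two-mapping design does not require.

## The simulator and what the tests show

The simulator is the package's study-condition generator, not a fixture:
seeded, byte-deterministic, with full truth tables (cell, transcript,
allele, amplicon strand, truncation, error-free genomic blocks). Defaults
encode the library architecture: 24-nt barcodes (≤ 48, pairwise edit
distance ≥ 8), 25-base polyA tract, anchor `AAGCAGTGGTATCAACGCAGAGTAC`,
TSO tail `ATGGG`. Error injection is i.i.d. per base (substitution,
insertion, deletion), qualities Q20 for clean and Q7 for error bases so
the qscore filters are exercisable. The accuracy benchmarks use 5%
substitutions and 2% insertions/deletions each — a deliberately harsh
setting around the upper end of modern long-read error rates — and 10,000
reads across 48 cells; smaller seeded libraries (hundreds to a few
thousand reads, 2–8 cells, 3–10 genes) drive the unit tests so the whole
suite runs in minutes on one CPU. Maternal fractions are exercised over
{0, 0.25, 0.5, 0.75, 1} with ~6,000 reads, recovering each within
binomial 3σ.

What the simulator does **not** emulate: homopolymer-biased and
signal-level Nanopore error structure, PCR duplicates and amplification
bias, 3′ coverage decay, expression distributions with realistic dispersion,
or genuine splice-site sequence context. Passing tests therefore establish
the correctness of the *rules* — scoring, thresholds, classification,
averaging, normalization — under controlled error processes, not
end-to-end performance on real flow-cell data, where mapping quality and
basecaller behaviour dominate.

## Numerical and degenerate-input conventions

Empty inputs return empty, well-typed results (empty FASTQ, zero reads,
empty SNP table, empty lncRNA reference with a warning). Ties in barcode
scoring are unassigned; ties in snapping resolve to the nearer annotated
edge (left on exact ties). Cluster-median edges use the sample median;
even support counts can give half-integer representative ends, which is
harmless because chain identity, not terminal ends, defines a model.
Duplicate VCF positions are an error; unsorted VCFs are sorted with a
message. All thresholds ship as function arguments with the defaults
above, so every boundary is configurable without code changes.
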