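---
title: "Dub-seq analysis: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dub-seq analysis: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dubseqr)
library(dplyr)
```

## The assay and the estimation problem

A Dub-seq library clones random sheared genomic fragments between two random
20-nt DNA barcodes (UP and DOWN) on a plasmid. Once the library is
characterized — each barcode pair associated with the genomic interval it
flanks — any pooled competitive-growth experiment reduces to counting UP
barcodes by amplicon sequencing (BarSeq). Fragments carrying genes that
benefit the host under a condition rise in frequency; the analytical problem
is to go from per-barcode read counts to per-gene fitness effects, with
honest uncertainty filters.

The package implements the full computational chain:

1. **BPseq** — extract UP and DOWN barcodes from reads that span both, and
   build the reference set of barcode *pairs*.
2. **BAGseq** — extract each barcode together with the genomic sequence
   downstream of it, map that tail to the genome, and resolve each barcode
   to a single insert junction.
3. **BPAG join** — combine pairs and junctions into reference fragments.
4. **BarSeq** — count UP barcodes per sample.
5. **Scoring** — fragment fitness scores, then gene scores by non-negative
   least squares (NNLS).
6. **Calling** — reliable and high-confidence effects, replicate
   consistency, and a shuffle-based false discovery rate.

## Barcode extraction

A barcode is accepted when the two 9-nt anchor sequences flanking it match
*exactly*, at a position within ±2 nt of the expected barcode start, and
every barcode base has Phred quality ≥ 20. Barcodes containing `N` are
rejected outright (the quality gate would usually catch them; the rule is
explicit). When several offsets match, the offset closest to the expected
position wins, ties going to the smaller offset. Anchors are
configuration ([`flank_spec()`]), not constants: they are vector-specific,
and the simulator writes its own into the specs it returns.

Two frequency filters remove PCR and sequencing artifacts, both using the
same inclusive "at least two times" rule judged against the *unfiltered*
table:

* **one-off filter** — a barcode with a Hamming-distance-1 neighbour
  survives only if its count is ≥ 2× the most abundant such neighbour.
  Neighbour search is exact enumeration (20 positions × 3 substitutions)
  against a hash of observed barcodes, O(60·n).
* **chimera filter** — a barcode *pair* sharing its UP or DOWN barcode with
  another pair survives only if its count is ≥ 2× the most abundant related
  pair.

Both rules compare against the single most abundant competitor, not the sum
— the quoted wording ("the most abundant similar barcode") is taken
literally.

## Mapping tails to the genome

BAGseq tails (≥ 15 nt downstream of the 3' anchor) are aligned with a
purpose-built seed-and-extend mapper: exact 15-mer seeds against a genome
k-mer index on both strands, ungapped extension along each seed diagonal,
and a single-indel rescue that merges runs on adjacent diagonals (trimmed
when chance matches extend across the indel point). A hit qualifies with
alignment block ≥ 15 nt and ≤ 1 indel; a tail must map to exactly one
location — hits in repeat regions are discarded. Pre-computed alignments in
PSL format can be imported instead ([`read_psl_hits()`]) and are subjected
to the same acceptance rules.

Coordinates are 0-based half-open internally and 1-based inclusive in
exported TSVs (stated in their headers). A junction is the first genomic
base of the insert adjacent to the barcode; its direction records which way
the insert extends. The BPAG join requires the same contig, inward-facing
directions, and a fragment length in [100, 6000] nt. The orientation check
is an addition beyond the length rule: junctions facing away from each
other cannot come from one molecule, and requiring them to face inward
prevents joining junctions of different plasmids that happen to sit at a
plausible distance.

## Fragment scores

For an experiment set, a barcode is *valid* if it has ≥ 10 reads in at
least one time-zero sample. For valid barcodes,

$$f_i = \log_2\frac{s_i + 1}{t_i + 1},$$

with $s_i$ the condition-sample count and $t_i$ the **sum** of counts over
the set's time-zero samples (sum, not mean — consistent with the
pseudocount of 1 in both numerator and denominator). Scores are then
median-centered so each experiment's valid fragments have median exactly 0.
There is no depth normalization at the counting stage; the ratio plus
median centering is the entire normalization.

## Gene scores by two-pass NNLS

The model: a fragment's expected fitness is the sum of the fitness scores
of the genes it covers *completely* (start to stop; containment is
inclusive and strand-agnostic), genes contribute independently, and
intergenic regions contribute nothing. With binary coverage matrix $A$
(fragments × genes) the positive pass solves

$$\min_{g \ge 0} \lVert A g - f \rVert_2^2 ,$$

via Lawson–Hanson NNLS (`pracma::lsqnonneg`). Ordinary least squares
overfits badly here (adjacent-gene columns are highly collinear), and the
non-negativity constraint is what lets the regression ignore noisy negative
fragments next to a genuinely beneficial gene. Deleterious effects are
estimated by a second pass on $-f$.

**Merging the passes.** How the two passes combine into one signed score is
genuinely open; we report `score = score_pos - score_neg`. For genes with
coherent fragment evidence at most one side is active, so the subtraction
reduces to whichever pass found the effect and introduces nothing
otherwise. Genes covered by zero valid fragments are reported *missing*,
never zero. Each condition sample is regressed independently; replicates
are never pooled before regression.

The mean score (average $f$ of covering fragments) is retained for
comparison: it inflates neutral genes whose covering fragments also carry a
causative neighbour, which is precisely the artifact NNLS removes — the
package's acceptance demo ({g1} f=3, {g1,g2} f=3, {g2} f=0) yields
regression scores (3, 0) where the mean gives g2 = 1.5.

**Gene pairs.** Epistatic contributions of adjacent genes (with their
intergenic region) are modelled by augmenting $A$ with one column per
adjacent pair, set for fragments covering both genes entirely, and
re-running both passes. A pair qualifies only if its score exceeds both
single-gene scores, is supported by ≥ 2 fragments, and passes in every
replicate of the condition.

## Confidence filters

An effect (gene × experiment) is **reliable** when all three hold:

1. **magnitude** — |regression score| ≥ 2;
2. **consistency** — two-tailed one-sample t-test of the covering
   fragments' scores, p < 0.05, against reference $r$ = the experiment-wide
   mean fragment score when that mean shares the gene score's sign
   (stricter), else 0. Single-fragment genes instead need |f| in the top 1%
   of the experiment's |fragment scores| (valid fragments only — scores
   exist only for those). Zero-variance fragment sets pass iff their common
   value differs from $r$ (the p-value limit is 0).
3. **noise** — per-fragment Poisson noise
   $\sqrt{1/(1+s) + 1/(1+t)}/\ln 2$, gene noise
   $\sqrt{\sum \nu_i^2}/n$, and $z = \text{mean}(f)/\text{noise}$ with
   |z| ≥ 4. The z statistic uses the fragment-score *mean*, exactly per its
   defining formula; the magnitude filter uses the regression score, which
   is "the" gene score of the method. `count_start` in the noise formula is
   the summed time-zero count $t$, consistent with the denominator of $f$.

At 4303 genes the |z| ≥ 4 filter implies ≈ 0.27 expected false positives
per experiment (two-tailed normal tail), the package's first analytic
acceptance quantity.

A reliable effect is **high confidence** if the gene has ≥ 2 covering
fragments, or some other experiment of the same compound shows |score| ≥ 2
(single fragments risk secondary mutations). Replicate consistency is
|score| ≥ 1.5 with the same sign in the paired replicate. There is no
multiple-testing correction beyond this filter scheme, by design.

**Shuffle FDR.** The barcode → fragment assignment is permuted uniformly
(equivalently, the coverage matrix's row labels), *mean* gene scores are
recomputed per experiment, the same reliable/high-confidence calling is
applied, and the mean shuffled high-confidence count is divided by the
genuine count. Default 10 shuffles, explicit seed. Using the mean score in
the shuffled replicates (and treating all score variability as noise) makes
the estimate conservative. A genuine count of zero leaves the rate
undefined (reported `NA`).

## The simulator

`simulate_experiment()` generates a random genome with non-overlapping
genes, a fragment library with Normal(2600, 700) insert lengths clamped to
the 100–6000 nt cloning window and unique random barcode pairs, reads for
all three assay types, and BarSeq counts. Defaults (50 kb genome, 40 genes,
500 fragments, 100 reads per fragment per sample, two time-zero samples,
two condition replicates) give each gene roughly 5–10 independent covering
fragments — the regime the method is designed for — while keeping any
simulation study fast; these are the problem sizes used throughout the test
suite and the acceptance script.

The count model is Poisson around a log-normal library-abundance baseline:
time-zero counts are Poisson with rate proportional to abundance; condition
counts multiply abundance by $2^{\sum_j a_{ij}\beta_j}$ and renormalize to
depth. Growth is collapsed into this fold-change — there is no explicit
generations parameter, because $\beta$ in log2 units is exactly the
quantity the scoring chain targets. The Poisson choice is the simplest
model consistent with the noise formula used by the z filter.

Reads carry a random-length 5' pad (5 ± 2 nt) to exercise the anchored
search window, configurable substitution errors and constant base quality,
and truth labels in read names; BPseq chimeras are injected at a
configurable rate with `chimera=1` labels. Every fragment emits at least
two characterization reads so that zero-error round trips reconstruct the
truth table exactly.

What the simulator does **not** emulate: instrument-specific error and
quality profiles, PCR duplicates beyond chimeras, abundance-dependent PCR
bias, unsequenced or multi-genome sources, and operon-driven expression
(effects are attached to genes directly, not to promoter context). Passing
tests therefore demonstrate the correctness of the algorithms under the
stated statistical model, not robustness to every artifact of real
sequencing data.

## Numerical notes and degenerate inputs

* NNLS is deterministic given $(A, f)$; no iteration seeds. Empty inputs
  (no valid fragments, no covered genes) yield empty results, not errors.
* Extraction ties: closest to expected start, then smaller offset.
* A tie among a barcode's top two locations (or top related pairs at
  exactly half) fails the inclusive 2× rule and discards the barcode.
* Fisher's exact test for the operon comparison is two-sided by summing
  hypergeometric probabilities ≤ the observed table's; the reported odds
  ratio is the sample (cross-product) ratio.
* The clone-count calculator implements
  $N = \ln(1-P)/\ln(1-\text{insert}/\text{genome})$ as printed and rounds
  up. For a 4.7 Mb genome, 3 kb inserts and $P = 0.99$ it gives ≈ 7212; a
  frequently quoted figure of ≈ 4610 for these inputs corresponds to
  $P \approx 0.95$, a discrepancy we document rather than reconcile.
* Single-end BPseq reads are assumed to carry both barcodes (one read, two
  flank specs); reads yielding only one barcode count as unusable, not as
  errors.

## Known limitations

The mapper is designed for desk-scale genomes (≲ 1 Mb index comfortably);
real-genome scale would call for a compiled index. Only substitution errors
are simulated in reads (indel errors are handled by the mapper but not
generated). The single-gene model absorbs intergenic effects into pair
terms only for *adjacent* genes; regulatory elements acting at a distance
are out of scope. DOWN-barcode counting is supported for concordance checks
but all fitness calculations use UP barcodes.
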