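---
title: "Methods: TE enrichment, motif affinity, and conservation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE enrichment, motif affinity, and conservation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical conventions that make runs exactly reproducible.

## Coordinates and peak windows

All intervals are 0-based half-open internally (`end - start` is the
length); RepeatMasker `.out` input, which is 1-based inclusive, is converted
on read and BED passes through unchanged.  A ChIP-seq peak is reduced to a
200 bp analysis window centered on its geometric midpoint
`floor((start + end) / 2)`; for even-length peaks this midpoint is the lower
of the two central candidates, a deterministic choice.  Whether a peak
caller's summit would be a better center than the geometric midpoint is
unknowable from interval input alone, so the midpoint is used throughout.
Windows that would run past a chromosome end are clipped and flagged:
flagged peaks still participate in interval statistics (enrichment,
partition, gene linking) but are excluded from sequence scanning, because
fabricating sequence for the missing bases would bias motif rates.  Peak
strand is ignored (ChIP-seq peaks are unstranded); TE strand is kept but all
distances and overlaps are computed on the forward strand.

Two peak sets are partitioned by window overlap (≥ 1 shared base).  Because
one window can overlap several on the other side, the intersection counted
from side A need not equal the intersection counted from side B; both
numbers are reported rather than reconciled.

## Enrichment z-scores

The enrichment statistic for a TE family is

$$z = \frac{x - \mu}{\sqrt{s}}$$

where $x$ is the number of *distinct* instances of the family overlapping at
least one real peak window, and $\mu, s$ are the sample mean and unbiased
sample variance of that count over `n_random` matched random peak sets
(default 1000; the estimator choice is immaterial at that depth but must be
fixed).  Counting distinct instances — rather than per-peak hits or
base-pair overlap — matches reporting enrichment as "numbers of instances";
an instance under two windows counts once, a window over two instances
increments both families.  Class-level scores aggregate family counts by
repeat class, so a class count always equals the sum of its member family
counts.  The per-peak alternative is available behind a flag.

The null model is *locally matched*: each chromosome is divided into fixed
1 Mb windows anchored at position 0, and for every real peak one random peak
of the same width is placed uniformly in the 1 Mb window containing the real
peak's midpoint (the last, partial window of a chromosome is used as-is; a
window too short for a peak falls back to whole-chromosome placement, which
is logged).  This conditions the null on the large-scale distribution of the
peaks themselves, so regional biases — uneven repeat density, assembly gaps,
chromosome-scale composition — cancel out of $z$.  Random peaks may overlap
each other and real peaks; nothing beyond uniform placement within the
window is imposed.  Units with zero variance across replicates are flagged
degenerate instead of being given a fake $z$ (0 when $x = \mu$, signed
infinity otherwise).

Enrichment calls use a strict $z > 3$ cutoff, reported separately for
families and classes, sorted by decreasing $z$.

Reproducibility: the master seed spawns one child seed per replicate, and
the child seeds are recorded on the result, so any single replicate can be
re-drawn without re-running the rest.

## PWM scoring and threshold calibration

A matrix's counts get a pseudocount of 0.25 per base before per-position
normalisation (the standard small-sample correction).  A word scores
$\sum_i \log_2 P_i(b_i) / P_{bg}(b_i)$; `N` contributes 0; the reverse
strand scores the reverse complement.  The background is the empirical
genome composition symmetrised across strands (A with T, C with G
averaged), and the same background is used for calibration and scanning —
calibrating against one composition and scanning another would silently
shift hit rates.

Thresholds are calibrated per matrix so that **a random 200 bp window
contains at least one hit (either strand) with probability 0.01** — a
per-window rate, not a per-position rate, because the affinity score is
defined per instance/window.  Calibration draws `n_mc` (≥ 1000, default
10,000) i.i.d. background windows and records each window's maximum score.
Achievable hit rates form a discrete set: a threshold either admits a score
level or it does not, and for short matrices the levels are far apart — at
width 8 a *single* word is already present in
$2(200 - 8 + 1)\prod_i P_{bg}(b_i)$ of windows, between 0.1% and 2.5%
depending on composition.  The calibrated threshold is therefore the score
level whose achieved rate is *closest* to the target; this is unbiased in
sign, whereas always rounding to the nearest rate above the target would
systematically overshoot.  One consequence is worth spelling out: an 8-mer
made of the background's *common* bases has a single-word floor above 1%,
so no threshold at all can reach the target for it.  Short fixture motifs
are therefore biased toward the background's rarer bases (as real short
GC-rich motifs — SP1, estrogen-response half-sites — are in AT-rich
genomes), which keeps the level spacing fine near 1%.  The achieved rate,
sample size, and seed are stored with the matrix as its calibration report.

## Transposon Affinity Score

For family $f$ and factor $t$,
$\mathrm{TAS}(f, t) = n_{\text{carrying}} / n_{\text{instances}}$, where the
denominator is the set of $f$'s instances overlapping ≥ 1 peak window (the
same set the enrichment count uses) and an instance *carries* $t$ when a hit
in an overlapping window has its matched bases intersecting the instance's
span.  The span requirement makes TAS a property of the TE rather than of
the peak; the looser "any hit in an overlapping window" rule is available
behind a flag.  With thresholds calibrated at 0.01, a family of unrelated
sequence has expected TAS ≈ 0.01, which motivates the interactor cutoff of
TAS ≥ 0.10 — ten-fold above chance — in at least one family.  The cutoff is
inclusive (a family at exactly 0.10 qualifies); the boundary convention is
stated because nothing forces either reading.  At small instance counts
(tens), TAS has large binomial noise and single families can cross 0.10 by
chance; interactor lists at those depths are screens, not calls.

The TE × TF matrix (absent combinations 0) is ordered by average-linkage
hierarchical clustering of Euclidean distances, rows and columns
independently, with input order never affecting values (ties in the
dendrogram are broken by the deterministic name sort applied beforehand).

## Spacing correlators

For factors $a, b$ every hit pair within a window adds one count at the
signed start-to-start distance $d = \mathrm{start}(b) - \mathrm{start}(a)$
on the forward strand, enumerating *all* pairs rather than nearest pairs
(the quantity of interest is how often the pair occurs at exactly $d$).
Same-factor histograms exclude a hit paired with itself but count distinct
hits in both orders, making them symmetric.  Swapping the factors mirrors
the histogram exactly, and total counts equal
$\sum_w |A_w||B_w|$ minus excluded self-pairs — both are enforced as tests.

The modal distance $d^\*$ (ties broken toward smaller $|d|$, then smaller
$d$) is scored with a permutation null: hit positions are redrawn uniformly
within each window, preserving per-window hit counts and motif widths, and
the maximum histogram count of each permuted set is recorded;
$p = (1 + \#\{\text{null max} \ge \text{observed}\}) / (n_{\text{perm}} + 1)$.
An explicit permutation null was chosen over an analytic one because the
pair-count distribution under heterogeneous per-window hit counts has no
convenient closed form, and the permutation scheme states its exchangeability
assumption plainly.  Raw p-values are reported per pair; no multiple-testing
correction is applied across factor pairs (the pair count is reported so
users can correct at their chosen level).

For families sharing a conserved core (the ~70 bp MIR core being the
motivating case), instances are globally aligned to the core with
Needleman–Wunsch (match +1, mismatch −1, linear gap −2; configurable, since
no alignment scheme is canonical for decayed repeats) via Biostrings.  The
report gives per-core-position identity (gaps count as mismatches), labels
positions covered by calibrated motif hits on the core, and flags
*site-creating mutations*: instance hits mapping to core positions where the
core itself has no hit of that matrix, together with the substituted
positions — the pattern by which point mutations (e.g. an A→G near the core
start) create new half-site instances.

## Gene association

A peak links to a gene when the peak *midpoint* lies within ±20 kb of the
TSS.  Point containment (rather than any-overlap of the window) keeps the
±20 kb bound exact; the any-overlap rule is behind a flag.  Transcript-level
annotations are collapsed to one TSS per gene (smallest coordinate on +,
largest on −) before linking, so genes rather than transcripts are counted.
Signed distances are strand-relative with upstream negative.  TE-to-TSS
histograms use the nearest TSS by absolute distance, ties broken toward the
smaller coordinate.  Category enrichment is a one-sided hypergeometric
upper tail with BH correction across categories within one gene set, against
a user-supplied background that must contain every tested gene (the natural
background being all linked genes).  The category table is a plain
gene-to-category TSV; no ontology content ships with the package.

## Synteny conservation

Syntenic blocks map genome-A intervals to genome B by linear interpolation
of endpoints (exact offset arithmetic when block lengths match, as in the
simulation); inverted blocks reverse endpoint order.  Projection round-trips
are exact by construction and tested.  A genome-A TE pairs with a genome-B
TE of the *same family* (class-level matching behind a flag) when the
reciprocal overlap
$\min(|p \cap t_b| / |p|, |p \cap t_b| / |t_b|)$ of the projection $p$
reaches 0.5 — the standard conservative criterion for "the same element",
exposed as a parameter since no published threshold exists for this
procedure.  The best partner per A-instance is kept (largest overlap, ties
toward the smaller B coordinate); TEs spanning block boundaries are matched
on their largest in-block fragment.

## The synthetic-data generator

The generator emulates exactly the structure the statistics assume:

* **Genome** — i.i.d. nucleotides at a configured GC content (default study
  uses 40%, mammalian-like).  The model's background is the *empirical*
  composition of the generated sequence, not the nominal GC, so calibration
  matches what is actually scanned.
* **TE families** — each family is a consensus sequence whose copies are
  placed uniformly without overlap among planted TEs and decayed by i.i.d.
  substitutions at a per-base divergence rate (default 0.08, giving the
  ~90% identity typical of recognisable ancient repeats).  Motifs are
  planted into the consensus as the matrix's maximum-probability word, and
  motif pairs at an exact start-to-start distance.  Same-class decoy
  families at equal copy number give the enrichment test a realistic
  negative set.
* **Peaks** — for a family with multiplier $k$ and background window-overlap
  probability $b$ (from its genomic footprint), each peak routes with
  probability $(k - 1)b$ to a uniformly chosen instance (window start
  uniform among all starts sharing ≥ 1 bp) and otherwise lands uniformly on
  the genome; the overall overlap rate is then $kb$ in expectation and
  $k = 1$ is exactly uniform placement.
* **Genes** — a configured fraction of TSSs lands within ±2 kb of a TE
  midpoint, the rest uniform.
* **Synteny** — genome A is cut into blocks, shuffled, a fraction inverted,
  and concatenated into genome B; in-block TEs are carried over with the
  conserved fraction, non-conserved copies have their B-side sequence
  overwritten with background bases, and per-family decoy annotations are
  planted at unoccupied B positions.

Every generator is a pure function of (configuration, seed): reruns are
bit-identical, and all recorded ground truth (planted families per peak,
near-TE genes, conserved pairs) is re-derivable from the outputs.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: insertion biology (no target-site
duplications, no nesting, no indels in decayed copies, so alignments of
simulated copies are gap-free in expectation), GC isochores and mappability
structure (the 1 Mb matching in the enrichment null exists precisely to
absorb such structure in real data, but the simulation gives it little to
absorb), transcript structure beyond a single TSS per gene, and any
realistic motif content beyond what is planted.

## Problem sizes and test design

The default verification runs use a 2 × 5 Mb interval-level genome with 50
families of 40–100 copies, 2000 peaks, and 200 random replicates for the
enrichment properties (null z-scores centred with unit scale, ≤ 2% of null
families above $z = 3$, a five-fold planted family recovered above $z = 3$
across 20 seeded replicates); threshold calibration and validation use
10,000 sequences each; spacing recovery uses 40 copies at divergence 0.05
with 1000 permutations.  These sizes put the Monte Carlo noise floor well
below every asserted tolerance while a full run of the suite stays in the
minutes range.  All dual-route checks (vectorised implementation vs.
brute-force oracle) run on 100 random small fixtures per operation.

## Known limitations

* The enrichment null matches location at the 1 Mb scale only; finer-scale
  composition matching (GC, mappability) is deliberately out of scope.
* $z$-scores are reported as-is, without p-values from a fitted null — the
  z > 3 convention inherits whatever non-normality the count null has at
  small $\mu$.
* TAS treats each instance as carrying/not-carrying; hit multiplicity within
  an instance is ignored.
* Synteny blocks are inputs; the package computes no whole-genome alignment,
  and real (length-mismatched) blocks are handled by linear interpolation,
  which is only as good as the block calls.
* Spreadsheet peak tables must be exported to TSV; there is no xls reader.
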