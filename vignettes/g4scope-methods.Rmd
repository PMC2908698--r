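---
title: "G4 DNA motifs in yeast: discovery, conservation and feature association with g4scope"
author: "g4scope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G4 DNA motifs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scope)
```

## The problem

G-quadruplex (G4) DNA is a four-stranded structure formed by stacked planar
quartets of Hoogsteen-bonded guanines.  Sequences with the potential to form
intramolecular quadruplexes — four or more tracts of at least three
consecutive guanines separated by short loops — occur throughout genomes, but
a pattern match alone says nothing about function.  Two complementary,
purely computational lines of evidence can: (i) evolutionary conservation of
the motif beyond what a neutral substitution process predicts, and (ii)
non-random association of motif locations with functional genome features.
`g4scope` implements both, end to end, together with a synthetic-data
generator that plants motifs, conservation signal and feature enrichment
with known ground truth, so that every statistical component of the pipeline
can be validated without downloading any genome.

## Motif model and scanner

A *G-tract* is a maximal run of `minTract` (default 3) or more guanines:
seven consecutive G's are one tract, never two.  `N` never matches and
terminates a run.  Motifs are built by greedy left-to-right chaining of
consecutive tracts: a chain extends while the gap (the *loop*) between two
tracts is at most `maxLoop` nucleotides, and every maximal chain of at least
four tracts becomes exactly one motif, spanning first-tract start to
last-tract end.  A region with more than four close tracts is therefore a
single motif with `n_tracts > 4` — such regions can fold into several
topologically distinct quadruplexes, and the *multi-tract fraction* is one of
the statistics the package compares between motif sets.

Numerical conventions worth stating:

* The loop test is `gap <= maxLoop`; a gap of `maxLoop + 1` breaks the chain.
  Because tracts are maximal, loops always have length at least 1.
* The default `maxLoop` is 25 nt, chosen to cover the longest loop observed
  in a characterized quadruplex structure (22 nt); the scanner accepts any
  threshold and the count of motifs is non-decreasing in `maxLoop` (a
  property the test suite asserts on every genome it generates).  One caveat
  follows directly from the merge rule: two distinct motifs separated by a
  gap between two thresholds become a *single* motif at the larger one, so
  the count can in principle decrease across a threshold that exceeds their
  separation.  On background sequence at yeast GC this never occurred in
  hundreds of test genomes; the property tests therefore plant motifs with
  separations beyond the largest threshold they scan, which makes the count
  strictly well-behaved on the tested grid.
* Both strands are scanned by default.  Minus-strand motifs are the G4
  motifs of the reverse complement reported on the forward axis, which is
  equivalent to chaining runs of cytosines by the same rule — the
  implementation does the latter, the test oracle does the former, and the
  two must agree exactly.  Opposite-strand overlapping motifs are kept as
  distinct records.
* Coordinates are 1-based closed `GRanges` internally (the Bioconductor
  convention); BED's 0-based half-open and wiggle's conventions are converted
  at the I/O boundary by `rtracklayer`, GFF3 is native.  There is exactly one
  conversion layer.

The scanner is validated against a brute-force oracle (character-level run
detection and an explicit chaining loop, with the minus strand handled by
actually reverse-complementing the sequence) on hundreds of random
sequences and all loop thresholds in 5–50.

Filtering reproduces the usual bookkeeping before conservation analysis:
motifs overlapping a telomere mask by at least 1 bp are removed,
mitochondrial motifs are removed when a nuclear-only set is requested, and
when the assembly carries multiple rDNA repeat copies only one designated
copy's motifs are kept.  Removal counts per reason are retained so that
"668 total, 552 after filtering"-style accounting is auditable.

## Motif-level conservation and the evolutionary null

Conservation is called per species from reference-anchored alignment blocks
(MAF input; blocks on the reference minus strand are flipped to
reference-forward at read time).  For each motif overlapping a block, the
motif's reference positions are projected through the alignment columns to
the ungapped coordinates they occupy in the species row; the species row is
degapped and re-scanned with the same motif model; and the motif is
*conserved* if any species motif overlaps the projected interval by at least
one position.  Conservation does not require identity — different loop
lengths, tract counts and sequences all count, which is the biologically
motivated criterion (the structure, not the letters).  A motif with no
aligned block in a species is *unalignable*, a distinct outcome from
*not conserved*.  Motifs spanning several blocks are conserved if any block
says so, since block boundaries are artifacts of the aligner.  The species
row is scanned on both strands by default (a quadruplex on the complementary
strand is still a quadruplex); forward-only is an option.

Significance of the conserved count uses an evolutionary null: each block's
species row is replaced by a row "evolved" from the reference under a 4x4
substitution matrix estimated from the aligned pair itself (counted over
non-gap columns, row-normalized with add-one smoothing), and conservation is
re-called.  The empirical p-value is the fraction of replicates whose
conserved count reaches the observed count, reported as `< 1/N` when none
does (the numeric value is then floored at `1/N`); the `(r+1)/(N+1)`
estimator is available as an option.  Design choices that the data do not
dictate, made once and documented here:

* *Matrix scope.* One matrix per block ("local") is the default; a single
  global matrix pooled over all blocks is an option.  Local matrices adapt
  the null to regional base composition.
* *Gap treatment.* Evolved rows reproduce the real species row's gap columns
  at the same positions, so alignment geometry is held fixed and only
  substitutions drive the null.  Reference-gap columns keep the real species
  base; reference `N` is copied.
* *Determinism.* Per-replicate, per-block seeds are derived by stable
  hashing of the master seed, so the p-value is invariant to block
  processing order and any stage can be re-run in isolation.

Calibration is checked empirically: on synthetic species pairs evolved
neutrally (no planted retention), the empirical p over 200 independent
datasets is tested for uniformity with a Kolmogorov–Smirnov test.  The
statistic is an integer count, so its empirical p is a step function for any
single data-generating configuration; the test suite uses 50 planted motifs
per 20-kb dataset at 5% divergence, which spreads the conserved count widely
enough (and varies the null across datasets enough) for the aggregate to be
indistinguishable from uniform at the KS level used.

## Nucleotide-level conservation

Within a G-tract of length $k$, a substitution at tract position $i$ leaves
intact runs of $i-1$ and $k-i$ guanines.  The position is **disruptive** iff
$\max(i-1, k-i) < m$ where $m$ is `minTract`: no remaining run can support
the tract.  For GGGG this makes the two middle positions disruptive and the
two ends non-disruptive; GGG is all disruptive; a tract of $2m$ or more G's
has no disruptive position.  This is the natural generalization of the
four-G example to arbitrary tract lengths; the equivalent "edge positions
beyond the core" formulation is provided as an alternative rule and shown in
the tests to coincide.  Classification ignores neighboring tracts (a
substitution rescued by a fifth tract elsewhere still counts as disruptive
for its own tract), matching the per-tract framing of the analysis.

Per-base conservation scores (phastCons-style posteriors in $[0,1]$) are
consumed from wiggle/bedGraph tracks.  Missing scores mean *unaligned*, are
kept distinct from zero, and are excluded from all means.  Two tests are
provided:

* **Motif vs flank** — per motif, the mean score inside the motif against
  the mean over the 100 nt on either side (truncated at chromosome ends);
  the per-motif indicator uses strict inequality (a tie is "not more
  conserved", the conservative choice for the subsequent exact binomial test
  of the indicator count against Binomial(n, 1/2)).  Flanks are used as-is;
  excluding flank positions that belong to adjacent motifs is available as
  an option.
* **Disruptive vs non-disruptive** — scores pooled by position class across
  motifs (tract positions only), compared by the two-sided Wilcoxon rank-sum
  test (exact enumeration up to combined n = 20 and no ties; otherwise the
  normal approximation with tie correction).  When a class is empty — e.g.
  every tract has exactly three G's — the means are reported and the p-value
  is flagged undefined rather than fabricated.

## Feature association

The association unit is the query region: the statistic is the number of
motifs with at least 1 bp of overlap with at least one reference feature,
where features may be expanded by a per-feature-set window (e.g. "within
500 nt of an ARS") and clipped at chromosome ends.  The null distribution
comes from 1,000 (by default) random region sets matched to the query per
chromosome in count and length multiset, each start uniform over the
placements that fit.  Random regions may overlap each other and anything
else — plain uniform placement, no masking — and strand is assigned
uniformly when the query is stranded.  Both tails are always computed
(under-association is biologically meaningful, e.g. depletion in essential
ORFs), equality counts toward both tails, and zero-extreme tails are floored
at `1/R` and labelled `< 1/R`.  Strand is ignored by default and respected
per feature set when configured.

Multiple testing across feature sets is controlled by q-values: the
Benjamini–Hochberg step-up by default (deterministic), or Storey's plug-in
estimate $\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda) m)$ at $\lambda = 0.5$
multiplying the same step-up, floored at $1/m$.  The method used is recorded
in the output; Storey q-values can differ slightly from BH and from other
implementations' smoothed $\pi_0$ estimates.

Calibration and power are checked on synthetic data: with features placed
independently of motifs, the fraction of datasets with $p_{over} \le 0.05$
must not exceed 0.07 over 200 datasets; with 200 features placed near
motifs with probability 0.8, $p_{over} \le 0.01$ must be reached in at
least 95% of datasets at $R = 1000$.

## The synthetic-data generator

`generateGenome()` draws i.i.d. background at a configurable GC content
(default 0.38, the yeast nuclear genome) and overwrites it with planted
motifs built from configurable tract-count, tract-length and loop-length
distributions.  The defaults (78% four-tract motifs, tract lengths mostly 3,
loops 1–10 from {A,T}) emulate the property profile of observed yeast motif
sets — mean around 4.3 tracts of mean length 3.3 with three stacked quartets.
Planted motifs never overlap and are separated by more than `maxLoop`, so
calls cannot chain across plants; background-arising motifs are permitted
and reconciled against the truth at scoring time.  Placement failure after
10,000 attempts is an error suggesting lower density.

`generateSpeciesPair()` emits gapless pairwise blocks: background evolved
under a known substitution matrix (or a scalar divergence, spread evenly
over the three alternatives), and each planted motif either copied intact
(probability `retention`) or actively broken.  Breaking substitutes every
third guanine in enough tracts to leave only three intact, which guarantees
the pattern no longer matches — a single substitution would not break a
motif with five or more tracts, so exact retention truth requires this
stronger disruption.  With `retention = NULL` motif positions evolve
neutrally, the regime used for calibration.  Gapless blocks are the default
deliberately: the conservation null preserves gap structure anyway, and
gapless truth keeps projection exactly testable.

`generateFeatures()` places each feature near a random planted motif with
probability `enrichment`, else uniformly; `generateScoreTrack()` draws
clamped-normal background (defaults near the magnitudes seen in yeast
phastCons tracks: background mean 0.64, motif boost 0.02, disruptive boost
0.04) and adds the boosts before clamping.  Every generator is a pure
function of its configuration and seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: alignment gaps and indel evolution (blocks are
gapless; the null's gap handling is exercised on hand-built blocks only),
regional base-composition and substitution-rate heterogeneity, repeat
structure (telomeric repeats, rDNA arrays), and any correlation between
features beyond planted motif proximity.  Conclusions about real genomes
still require the real inputs.

## Worked example

```{r example}
sim <- generateGenome(c(chr1 = 50000L), gc = 0.30, nMotifs = 20L, seed = 1)
motifs <- scanG4Motifs(sim$genome, maxLoop = 25L)
motifs
head(as.data.frame(motifProperties(motifs)), 3)

pair <- generateSpeciesPair(sim$genome, sim$truth, divergence = 0.1,
                            retention = 0.8, seed = 2)
table(callConservation(pair$blocks, sim$truth, "sp")$call)
nullConservedCount(pair$blocks, sim$truth, "sp", nReps = 200L, seed = 3)
```

## Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale: 10–20 kb genomes for scanner validation (100 sequences, four
loop thresholds), 200 calibration datasets at 20 kb / 50 motifs / 500 null
replicates for the conservation null, and 60-kb two-chromosome genomes with
200 features for association calibration (200 datasets) and power (60
datasets at R = 1000).  These sizes were chosen to give the calibration
checks enough resolution (binomial/KS error well below the tolerances
asserted) while keeping a full run in minutes.  All randomness flows from
explicit master seeds through `deriveStageSeed()`, so every number in the
outputs is exactly reproducible.

## Known limitations

* The scanner models the canonical intramolecular pattern only: no
  thermodynamic scoring, no two-tract ("G2") quadruplexes, no RNA G4s.
* The evolutionary null models substitutions only; indels are held fixed.
* Storey q-values use the fixed-lambda plug-in, not a smoothed estimator.
* The mitochondrial analysis is a filtering/association configuration, not
  a separate model; mitochondrial conservation cannot be assessed without
  mitochondrial alignments.
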