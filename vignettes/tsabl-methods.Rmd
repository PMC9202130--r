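---
title: "Trait-specific classification of GWAS loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-specific classification of GWAS loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsabl)
```

## The problem

Genome-wide association studies identify loci — clusters of variants in
linkage disequilibrium — associated with complex traits, but rarely identify
which variants are functional or through which tissues they act. tsabl asks
a discriminative question: given the genomic annotations overlapping a
locus, can we tell loci of one trait group (say, platelet traits) apart from
loci of *all other* complex traits? A model that can is evidence that the
trait's loci carry a recognizable regulatory signature, and its scores can
rank individual variants — genome-wide, or inside fine-mapping credible
sets — by how much they look like the trait's known loci.

## The locus unit

Variants are grouped into loci by transitive LD clumping: two variants
belong to the same locus whenever they are connected by a chain of pairwise
R² ≥ 0.7. Formally, loci are the connected components of the graph whose
vertices are the lead variants plus their proxies and whose edges are the
supplied LD pairs at or above the threshold. Components are computed with
igraph; identifiers are assigned in genome order so the result does not
depend on input row order. Loci with more than 1000 variants are removed
(long-range LD regions that would otherwise dominate interval overlap), and
associations in the HLA region (chr6:29,670,261–33,104,175, 1-based
inclusive) are excluded up front for the same reason.

A locus is **positive** for a trait group when any member variant has a
genome-wide-significant association (p < 5×10⁻⁸) with any phenotype of the
group; it is **excluded** from the negative pool when any member shows even
modest association (p < 0.05) in available summary statistics; otherwise it
is **negative**. When a phenotype has no summary statistics, the modest-
association removal is impossible and non-positive loci stay negative —
the same asymmetry the thresholds imply.

## Feature encoding

Each locus is a feature vector over four blocks:

* **Annotation tracks** — one binary column per track; 1 iff any member
  variant overlaps any interval of the track. BED intervals are 0-based
  half-open, variant positions 1-based, so the test is (pos − 1) ∈
  [start, end) — bedtools semantics. Indels are tested at their start
  position only; since only the recorded position is tested for every
  variant, this is the same rule stated explicitly. The overlap join is a
  `data.table::foverlaps` interval join on [start, end − 1] closed integer
  intervals, which is exactly equivalent.
* **Nearest-gene tissue expression** — the nearest gene is the expression-
  table gene on the locus chromosome whose start lies closest to the locus
  center. The center is defined as `round((span_min + span_max) / 2)`; the
  original description leaves "locus center" undefined, and the integer
  midpoint of the variant span is the simplest reading. Equidistant genes
  are broken toward the smaller start, then the lexicographically smaller
  gene id, for determinism. A tissue bit is 1 iff that gene's expression-
  specificity t-statistic ranks in the top 10% of the tissue's column
  (rank ≤ ceiling(0.10·n) by descending t-statistic, ties by gene id).
* **Conservation** — the maximum member phastCons-style score, missing
  scores contributing 0.
* **Variant count** — the locus variant count, z-scored over the encoded
  locus set. "Normalized variant number" is not defined further in the
  original description; the z-score is the conventional reading and is
  scale-safe under an L1 penalty. The mean and standard deviation are
  persisted with the feature build so a single SNP can later be encoded as
  a 1-variant locus under the *training* constants — this makes the
  single-SNP encoding of a singleton locus bit-for-bit identical to its
  locus encoding, a property the tests assert.

Columns are sorted by name within blocks, making the matrix independent of
input order.

## Design construction

Models must generalize to loci of unseen traits, so the split and the
class-matching are constrained:

* **Train/holdout split** — within every exact variant-count stratum,
  ⌊2/3·n⌋ loci go to training and the rest to holdout (60 loci of count 10
  split 40/20), preserving the variant-count distribution on both sides. A
  seeded repair pass then swaps same-count loci between the partitions
  until every trait's positive count in training is within one locus of
  2/3 of its positives, with a 10,000-swap budget. The stratum rule and the
  per-trait ratio can conflict in principle; the repair pass — accept the
  first same-count swap that strictly lowers the summed deviation — is this
  package's concrete reading of a "semi-random" constrained split, and it
  terminates deterministically given the seed.
* **Count-matched negatives** — each positive is tied to 6 negatives whose
  variant count differs by at most 10 (positive count < 100) or at most 50
  (count ≥ 100). Positives are processed in ascending count order so
  scarce small-count positives get first pick; negatives are drawn
  uniformly (seeded) from the eligible set and used at most once per trait
  design, preventing duplicate rows. Positives without six eligible
  negatives are dropped and reported. The 1:6 imbalance is a design
  property, deliberately not reweighted in the loss.

## The trait model

The classifier is an L1-penalized (LASSO) binomial logistic regression,
fit with glmnet — binary annotation matrices are sparse and the penalized
path exploits that. One **trial** is: stratified 10-fold cross-validation
of the AUC over a geometric grid of 100 lambda values spanning four orders
of magnitude below the data-derived maximum; selection of the
one-standard-error lambda (the largest lambda whose mean CV AUC is within
one SE of the maximum — favoring sparser models); and a refit on the full
design at that lambda. Folds are stratified by class so every fold contains
positives; if a fold assignment still misses a class it is reshuffled with
a new seed, up to five attempts. The coordinate-descent convergence
threshold is 1e-5: on designs of this shape it selects the same lambda and
support as the stricter library default at roughly half the cost.

Fifteen trials are run with consecutive seeds, each trial's training AUC is
computed in-sample on the full training design, and the trial with the
median training AUC becomes the trait model (the lower median for an even
number of surviving trials; AUC ties broken by trial seed so the choice
does not depend on enumeration order). Whether the original selection used
in-sample or cross-validated training AUC is not stated; in-sample is the
plainer reading of "training AUC" and is used here. Repeated-trial median
selection damps the fold-assignment randomness that a single
cross-validated fit inherits.

Coefficients are reported on the standardized (per-SD) scale: glmnet
standardizes internally, and the fit is re-parameterized against the stored
column means and standard deviations so that scoring new loci or SNPs with
the stored constants reproduces the identical linear predictor.

A model is **informative** when its holdout AUC is at least 0.70 and the
absolute training–holdout AUC difference is at most 0.02 (both inclusive,
with a 1e-9 epsilon guarding the floating-point boundary). The AUC is the
Mann–Whitney probability that a random positive outscores a random
negative, ties at one half, computed from rank sums; tests cross-check it
against exhaustive pair counting and against pROC.

One degenerate corner is worth recording: with a feature that separates the
classes *perfectly*, every CV fold reaches AUC 1 with zero standard error
already at the largest lambda, so the one-SE rule selects the empty model.
This cannot arise from the generator below (overlap probabilities are
bounded away from 0 and 1) and is not observed on real annotation data; the
unit tests therefore plant a near-separating feature rather than a perfect
one.

## FDR calibration and downstream use

Score cutoffs are calibrated on the holdout design only. For a candidate
cutoff t, the empirical FDR is the fraction of negatives among holdout loci
scoring ≥ t; the cutoff for level α is the smallest t with empirical
FDR ≤ α (the most permissive calibrated threshold), making the achieved FDR
conservative by construction at the holdout's 1:6 class composition. That
composition is an interpretation caveat: genome-wide, the base rate of
trait loci is far lower, so the calibrated levels are relative to the
matched-design composition, not a genome-wide prior.

Genome-wide SNP hit lists take every scored SNP at or above the level-0.01
cutoff, minus any rsID used as a model-building positive. Credible sets
(consumed as input, never computed here) are prioritized at FDR levels
0.10/0.25/0.50: a set is *reduced* at a level iff at least one but fewer
than all members clear the cutoff, and the summary is the reduced fraction
among multi-SNP sets. Because cutoffs are monotone non-increasing in the
level, prioritized member sets are nested across levels. Members are also
emitted ranked by score for threshold-free use.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the pipeline
consumes, with known ground truth:

* locus variant counts from `1 + NB(mu = 19, size = 1.2)` — overdispersed
  with mean ≈ 20, matching the ≈ 22 variants/locus of large published locus
  tables;
* loci placed in disjoint, 200 kb-spaced windows on 22 autosomes, members
  ≈ 100 bp apart; LD pairs synthesized as a random spanning tree of
  R² ∈ [0.7, 1] per locus plus within-locus pairs on both sides of the
  threshold and cross-locus noise below it, so clumping the emitted pairs
  reproduces the intended partition exactly (a round-trip the tests
  assert);
* per-(locus, track) overlap drawn once — probability 0.10 background,
  odds-scaled (odds ratio 3 → probability 0.25) for a trait's informative
  tracks in its positive loci — and planted at a random member variant, so
  the locus-level OR encoding is exercised nontrivially;
* association p-values consistent with the intended labels (positives get
  p < 5×10⁻⁸ leads; negative-pool members get summary-statistic p > 0.05;
  "excluded" loci get one member with 0.001 < p < 0.05);
* an expression table with one candidate gene near each locus center plus
  background genes; positive loci have their candidate gene planted in the
  trait tissue's top decile with probability 0.6;
* uniform conservation scores (no planted conservation signal — the
  conservation and variant-count features act as realistic nuisance
  columns);
* multi-SNP credible sets for positive loci with a designated causal
  member that preferentially overlaps planted intervals.

The default scale — 400 positives, 3000-locus negative pool, 300 tracks
with 20 informative at odds ratio 3 — is the standard benchmark condition
used by the acceptance tests and `scripts/acceptance.R`. The chance-level
control runs disable *both* planted signals (track enrichment odds 1 and
no planted expression signal — either alone is real signal) and use 300
positives and 150 tracks: the width of the null AUC sampling distribution
is set by the holdout design size, not the track count, and this scale
keeps twenty fully trained control runs affordable.

Two behaviors of the estimator on chance-level data are worth knowing.
Holdout AUCs concentrate tightly around 0.5, as they must. Model
*sparsity*, however, is not guaranteed: on a flat cross-validated AUC
curve (SE ≈ 0.02) the curve's maximum lands at an arbitrary lambda, and
in a minority of seeds it drifts toward the dense end, where the one-SE
rule then selects a model with many small noise coefficients. Those dense
null models still score at chance out of sample; sparsity under the null
is a tendency of the one-SE rule, not an invariant.

What the generator does **not** emulate: realistic LD decay, allele
frequencies, population structure, correlated annotation tracks
(real ENCODE/Roadmap tracks are strongly correlated within tissues),
pleiotropic positives shared between simulated traits, or conservation
signal. Passing tests therefore demonstrate that the pipeline recovers
planted locus-level enrichment and calibrates its thresholds correctly —
not that any particular real trait is predictable, nor how collinear real
annotations will distribute coefficients among themselves.

## Numerical choices and degenerate inputs

* Constant (zero-variance) feature columns pass through standardization
  with scale 1 and receive zero coefficients.
* A zero standard deviation of variant counts (all loci the same size)
  makes the normalized-count feature all zeros rather than undefined.
* Loci on chromosomes with no expression-table gene get all-zero tissue
  bits, with a warning.
* Missing conservation scores and missing per-SNP baseline scores are 0;
  in the `one_minus_min` baseline aggregation (for e-value-like scores
  where smaller is more functional) unscored members are ignored and a
  fully unscored locus returns 0.
* LD pairs naming unknown variants are ignored with a warning; malformed
  association rows are dropped and counted, never fatal.
* An FDR level no cutoff can attain is marked unattainable; selection at
  such a level returns an empty hit list with a warning.

## Problem sizes used in the shipped tests

The acceptance tests run the full protocol — 15 trials of 10-fold CV — on
five seeds at the standard benchmark condition, ten seeds for the
planted-track recovery average, and twenty chance-level control runs at the
reduced control scale; unit tests use a smaller bundle (60 positives, 40
tracks) with a 5-trial pipeline for structural checks. These sizes were
chosen so the whole suite exercises every stage at realistic shapes while
remaining comfortably runnable on a single CPU.

## Worked example

```{r example, eval = FALSE}
library(tsabl)

# simulate a benchmark bundle and run the full pipeline
bundle <- simulate_dataset(sim_config(seed = 1))
pl <- run_trait_pipeline(bundle, seed = 1)
pl$evaluation$summary

# planted-track recovery of the trained model
planted_signal_report(pl$traits$trait1$model, bundle$truth)

# calibrated FDR cutoffs (holdout only)
pl$traits$trait1$fdr_table

# prioritize the simulated credible sets with per-SNP scores
snps <- bundle$variants[, c("rsid", "chrom", "pos")]
sc <- score_snps(pl$traits$trait1$model, snps, bundle$tracks,
  bundle$expr, bundle$cons,
  norm_constants = pl$features$norm_constants
)
prioritize_credible_sets(bundle$credible_sets, sc,
  pl$traits$trait1$fdr_table,
  levels = c(0.10, 0.25, 0.50)
)$summary
```

## Known limitations

* The FDR levels are calibrated at the matched 1:6 holdout composition
  (see above) — they are comparative, not genome-wide error rates.
* Only single-label (one-vs-rest) models are fit; no elastic-net or
  multi-label variants.
* Credible sets, baseline per-variant scores (CADD/GWAVA/DeepSEA-style)
  and LD tables are consumed as inputs; the package aggregates and applies
  them but never computes them.
* Coordinates are used as given — no liftover or genome-build validation.
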