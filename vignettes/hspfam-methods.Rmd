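---
title: "Classifying heat shock protein families from combined sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heat shock protein families from combined sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Heat shock proteins (HSPs) are molecular chaperones grouped by molecular
mass and function into six families — HSP20, HSP40, HSP60, HSP70, HSP90 and
HSP100. Assigning a bare amino-acid sequence to its family is a routine
annotation task, and curated HSP collections are strongly imbalanced: the
HSP40 family dominates, the HSP90 family can be twenty times smaller. A
classifier trained naively on such data drifts towards the majority family.
`hspfam` implements a complete sequence-based pipeline for this setting:
four complementary feature encoders, a from-scratch SMOTE oversampler that
balances family counts, a one-versus-one RBF-kernel SVM with grid-searched
hyper-parameters, and jackknife (leave-one-out) evaluation reporting
per-family sensitivity (Sn), specificity (Sp), Matthews correlation
coefficient (MCC) and accuracy (Acc) plus overall accuracy (OA).

## The feature encoders

**SAAC — split amino acid composition.** The sequence is cut into an
N-terminal and a C-terminal segment whose lengths are in the golden ratio
φ = (1+√5)/2, and the 20 residue frequencies are counted per segment
(40 features at the default one-step split). The cut point is
`L_N = round(L / φ)` with round-half-up; the remainder forms the C segment.
The split recurses for deeper variants (`depth` 2 gives the four segments
NN, NC, CN, CC, 80 features). We default to `depth = 1` — the plain N/C
split — and support deeper splits as an option. Because the two children of
a split are unequal, the minimum admissible sequence length grows faster
than `2^depth`; `golden_split()` reports the exact minimum on error
(depth 3 needs at least 10 residues, not 8).

**DC — dipeptide composition.** The 400 ordered adjacent residue pairs,
`f_i = m_i / (L - 1)`. Captures first-order neighbour information.

**CTF — conjoint triad feature.** Residues are first mapped to 7 groups by
side-chain dipole moment and volume ({A,G,V}, {I,L,F,P}, {Y,M,T,S},
{H,N,Q,W}, {R,K}, {D,E}, {C}); the 343 group triads over all windows of
three consecutive residues are counted, `x_i = n_i / (L - 2)`.

**PseACS — pseudo-average chemical shift.** Each residue is substituted by
its averaged backbone NMR chemical shift for four nuclei (¹⁵N, ¹³Cα, ¹Hα,
¹HN), turning the sequence into four numeric series; for each series the
lag features `φ(λ) = mean_k (A_k - A_{k+λ})²` are computed for
λ = 0 … 54, giving 4 × 55 = 220 features. This injects a coarse
secondary-structure signal, since averaged chemical shifts track backbone
conformation. Two numerical choices deserve note:

* *The lag-0 term.* The defining formula evaluates to exactly 0 at λ = 0.
  We default to emitting that literal zero (`tier0 = "literal"`), keeping
  the block faithful to the formula; `tier0 = "mean"` replaces it by the
  sequence's mean shift, which carries composition information instead of a
  constant. The choice does not affect any distance computed on the block
  in literal mode beyond adding a constant-zero coordinate.
* *The shift table.* The bundled table
  (`inst/extdata/acs_table_synthetic_default.tsv`) contains representative
  per-residue averaged shifts in the range of public BMRB statistics; it is
  a synthetic stand-in, clearly labelled as such, and overridable via
  `read_acs_table()`. The lag features are invariant to any constant offset
  of the table (differences cancel), so only between-residue contrasts
  matter; classifiers built on these features are insensitive to the
  table's absolute calibration but do depend on its contrasts, so results
  should not be expected to match bit-for-bit any particular server's
  table.

Feature order is frozen for reproducibility: residues alphabetical,
dipeptides first-residue-major, CTF triads lexicographic over group
indices, PseACS nuclei in the order ¹⁵N, ¹³Cα, ¹Hα, ¹HN with lags
ascending. The default combined vector is 40 + 400 + 343 + 220 = 1003
features with a recorded block index.

## SMOTE balancing

`smote_class()` implements the classic synthetic minority oversampling:
each synthetic point is `x + u (x_nn - x)` with `x` a minority sample,
`x_nn` one of its `k = 5` nearest in-class neighbours (Euclidean distance
on the raw feature vectors) and `u` uniform on [0, 1].
`balance_to_majority()` processes minority classes smallest-first and tops
each up to the majority count exactly; original rows are preserved
verbatim and synthetic rows carry a provenance flag. When `n_new` is not a
multiple of the class size, base samples are cycled in order one pass at a
time and the remainder is assigned by a seeded shuffle — deterministic and
uniform. The effective neighbour count is `min(k, n_class - 1)`; a class
of two therefore interpolates along its single segment, and a singleton
class is a hard error (no segments exist).

## The classifier

The SVM is libsvm's C-classification machine (via `e1071`) with the RBF
kernel and native one-versus-one decomposition: `k(k-1)/2` pairwise
machines combined by majority vote. Training rows are sorted by label so
the internal class order — and hence vote tie-breaking — is the
alphabetical label order, fixed across platforms. The defaults follow the
canonical libsvm practitioner grid, cost `2^-5 … 2^15` and gamma
`2^-15 … 2^3` in multiplicative steps of 4, selected by stratified 5-fold
cross-validated overall accuracy with ties resolved towards the smallest
cost, then the smallest gamma. Frequencies lie in [0, 1] but PseACS
magnitudes do not, so features are min-max scaled to [0, 1] with
statistics fitted on the training data only (`scaling = "none"` is
available). Hyper-parameters are tuned once on the full training set and
held fixed during resampling — tuning inside every jackknife fold is
prohibitively expensive at leave-one-out scale and the package makes the
single-tuning choice explicit in the report metadata.

## Evaluation protocols

`jackknife()` performs leave-one-out evaluation and reports the Sn, Sp,
MCC and Acc of each family (one-vs-rest reductions of the k×k confusion
matrix) plus the overall accuracy `OA = Σ TP_i / N`. A zero MCC
denominator is reported as MCC = 0 with an explicit flag.

Two SMOTE placements are provided:

* **as-paper** (default): the dataset is balanced once up front and the
  leave-one-out loop runs over all samples, real and synthetic. This is
  the common balance-then-validate practice. It is also optimistic:
  synthetic test points are interpolations of points that remain in the
  training fold.
* **leakage-safe**: only real samples are held out, and SMOTE is
  re-applied to the remaining data inside every fold, so no synthetic
  point ever derives from the test sample. This is the honest estimate of
  generalisation to new sequences.

The package keeps both because their gap is itself informative — the
as-paper protocol should never score below the leakage-safe one on
overlapping classes, and the acceptance suite checks that direction
empirically.

In as-paper mode scaling and the tuned (cost, gamma) are fitted once on
the balanced data (consistent with tuning once). With the solution thereby
fixed, removing a sample that is not a support vector of any pairwise
machine provably leaves the fitted decision functions unchanged, so its
leave-one-out prediction equals the full-model prediction; only
support-vector folds are retrained. This is an exact shortcut, not an
approximation, and it makes leave-one-out at n ≈ 500 with 1003 features
tractable on one CPU. Leakage-safe mode cannot use it (the training set
changes per fold) and retrains every fold. `cross_validate()` offers
stratified k-fold CV as a cheaper alternative protocol, and
`evaluate_independent()` scores a held-out dataset against a trained
model, warning if test ids overlap the training ids.

## The synthetic data generator

Real HSP benchmarks cannot ship with the package, so `simulate_dataset()`
generates datasets that emulate their *structure*: six classes with the
benchmark's imbalanced profile 357/1279/163/283/58/85 by default
(scalable), sequence lengths uniform on 80–400, and class-specific residue
compositions. Each class profile is `(p0 + divergence · d_c) / (1 +
divergence)` where `p0` is one shared Dirichlet(5·1) draw and `d_c` a
class-specific Dirichlet(1) draw: `divergence = 0` collapses all classes
onto one distribution (a null model), large values give well-separated
compositions. An optional `dipeptide_bias` mixes class-specific first-order
transition preferences into an otherwise i.i.d. sampler. The default
divergence of 1 produces moderate overlap, which is what distinguishes a
plausible protein-family problem from a trivial one.

What the generator does **not** emulate: domain architecture, homology
structure, motif grammar, length–family correlations. Passing tests on
simulated data therefore demonstrate that the pipeline's machinery is
correct and that it recovers compositional signal where it exists — not
that any particular accuracy will be achieved on real HSP collections.

A note on the null baseline: with `divergence = 0` and **no** balancing,
the best achievable classifier is the majority vote, so jackknife OA
should sit at the majority-class proportion — this is the analytic
expectation the test suite checks. After SMOTE balancing that baseline is
1/6 by construction, so the null-model check runs the unbalanced pipeline.

## Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen for a single CPU:

* Structural checks (encoder dimensions, metric identities) run on single
  sequences or thousands of tiny random cases.
* The SMOTE end-state check uses the full 2225-sequence benchmark profile
  with 6 cheap features.
* The high-divergence recovery check uses 6 classes, 300 sequences
  (75/60/55/45/35/30, balanced to 450) with the full 1003-feature
  encoding — leave-one-out there exercises the exact support-vector
  shortcut. The null-model check uses the benchmark's imbalance ratios
  scaled to 100 sequences, averaged over 5 seeds.
* The leakage comparison pairs the two protocols over 10 seeds on a
  42-sequence 3-class dataset with moderate divergence.

Coarse hyper-parameter sub-grids are passed explicitly in these runs; the
package defaults remain the full practitioner grid.

## Known limitations

* The SMO core is delegated to libsvm; the package owns everything around
  it (scaling, selection, OVO determinism) but does not re-derive the
  optimiser.
* PseACS depends on the shift table's contrasts; the bundled table is a
  documented synthetic stand-in, not a calibrated reference.
* The as-paper protocol's accuracy on balanced data is an optimistic
  quantity by construction; use the leakage-safe protocol when an unbiased
  estimate matters.
* Redundancy reduction of input collections (e.g. removing sequences with
  ≥ 40 % pairwise identity) is upstream preprocessing and out of scope.
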