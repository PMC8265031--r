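---
title: "Exact and approximate explanations for a kNN diagnostic classifier"
author: "shapknn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact and approximate explanations for a kNN diagnostic classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapknn)
```

## The classifier and its value function

The object being explained is a k-nearest-neighbor (kNN) diagnostic
classifier of the kind used for serum proteomic testing: eight
mass-spectral feature intensities (named by their approximate m/z
positions, `vsFeatures()`), a reference set of 26 labeled samples (13
Good, 13 Poor), `k = 7`, and a binary output encoded Poor = −1,
Good = +1. A `ReferenceSet` object carries all of this.

Game-theoretic attribution needs a *value function* `f(S)`: the
prediction obtainable from a feature subset `S` alone. For kNN,
"retraining on a subset" is exact and cheap — distances are simply
computed using only the subset's coordinates — so `f(S)` can be
enumerated for all `2^8 = 256` subsets (`subsetValueTable()`). The
empty subset is defined as uninformative, `f(∅) = 0`, which makes the
efficiency identity `Σψ + f(∅) = f(M)` read "the attributions share
out the ±1 classification".

Two conventions had to be fixed because the deployed test does not
publish them:

* **Distance.** Euclidean distance on log-transformed intensities
  (`distance = "log-euclidean"`), with a raw-scale switch. Intensities
  are positive and roughly log-normal, and the test's own
  standardization practice for surrogate modeling works in log space,
  so log-space geometry is the consistent choice.
* **Ties.** Distance ties at the k-th neighbor are broken in favor of
  the lowest reference-sample index. Ties have probability zero for
  continuous synthetic data; the rule exists so that identical inputs
  always give identical outputs. Squared distances are accumulated
  coordinate-wise by explicit differences (never the expanded
  quadratic form), so a coordinate on which the instance equals every
  reference contributes exactly zero and cannot perturb tie structure
  through floating-point noise.

`k` and the reference-set size are configurable so that small panels
can be verified by brute force.

## Exact Shapley values and the instance taxonomy

`shapleyValues()` evaluates the subset-sum form of the Shapley value
with coalition weights `|S|!(m−|S|−1)!/m!` computed from exact integer
factorials and divided once — for `m ≤ 8` every weight is an exact
ratio of small integers, so the only floating-point operations are the
final multiplications and additions, and identities hold to 1e−12 or
better. An independent permutation-averaging oracle
(`shapleyPermutationOracle()`, factorial cost, limited to `m ≤ 8`)
cross-checks the weighted sum in the test suite on every panel size up
to 6.

Instances fall into a taxonomy read off the exact values
(`classifySVPattern()`):

* **uniform** — all Shapley values equal (tolerance 1e−9, exposed).
  Since exact-mode tables are ±1-valued, equality forces the common
  value ±1/m. Uniformity is defined by *equality*, not by the value
  1/8, so the tag generalizes to other panel sizes.
* **boundary** — the two probe features (default the dominant pair
  11529/11685) carry unequal values, the signature of instances near
  the decision surface.
* **other** — the remainder.

One naming note: the canonical panel has eight features, although
enumerations of the mass positions in the literature often list seven;
the 11685 feature (also written 11686) completes the panel and is the
default second probe feature.

## Pairwise interaction metrics

All four metrics are computed from the cached 256-entry table, so the
classifier is evaluated `2^m` times per instance regardless of how many
metrics are requested.

* `siiPair()` keeps the original pair-index normalization of the
  Shapley interaction index; treatments that define the index for the
  two-feature *subset* double it, so a `doubled` flag is exposed for
  cross-library comparison rather than silently choosing a side.
* `stiiMain()` is the single-feature classification relative to the
  null value; together with `stiiPair()` it satisfies second-order
  efficiency, which the tests assert on random tables.
* `harsanyiPair()` uses only the four smallest coalitions — pure
  pairwise synergy.
* `sps()` is asymmetric by design: `sps(table, i, j)` conditions on
  feature `i` and attributes feature `j` within coalitions already
  containing `i`, the first term of the exact split of `ψ_j`
  (`shapleySplit()`), whose two terms recompose `ψ_j` to 1e−12. Both
  table entries in its bracket contain the conditioning feature, so the
  sum vanishes whenever all subsets containing that feature classify
  alike — on uniform instances it is identically zero.
* Harsanyi-dividend and partial-sum diagonals are *undefined*, stored
  and serialized as absent (`NA`), never zero-filled, so "not defined"
  and "computed as 0" stay distinguishable.

For a uniform Good instance the analytic constants are: Shapley values
1/8, off-diagonal SII −1/14, STII −1/4, HD −1, SII main effects 5/8,
STII main effects +1, and all partial sums 0; signs flip for uniform
Poor. The acceptance tests verify all of them at 1e−12.

## SHAP approximations

The three approximations replace the retrained `f(S)` by a conditional
expectation of the *full-panel* classifier and push the expectations
through the same exact weighted sum over the complete subset lattice
(no weighted-regression shortcut), which keeps the three variants
structurally comparable to the exact computation:

* **kernel SHAP** (`independent_reference`): for each subset, average
  the classifications of the 26 hybrids that keep the instance's
  values on `S` and take one reference sample's values elsewhere.
  Fully deterministic.
* **multivariate Gaussian**: mean and covariance fitted to the log
  intensities of the 26 references; the off-`S` coordinates are drawn
  from the exact Gaussian conditional (default `N = 1000` draws per
  expectation).
* **Gaussian copula**: per-feature empirical margins (probability
  integral transform) plus a Gaussian copula fitted on the transformed
  scores; conditioning happens in score space and the draws are mapped
  back through the inverse transform before classification.

Numerical choices:

* The empty-subset expectation is computed by the same machinery with
  *all* features unknown, not forced to 0. For a balanced,
  self-consistent reference set it equals 0 exactly under kernel SHAP
  (the hybrids are the references themselves) and is ≈0 for the
  sampling variants; the value is stored per attribution, and
  efficiency `Σφ + E[f(∅)] = f(M)` holds by construction for all
  three variants.
* Covariance/correlation estimates from 26 strongly correlated samples
  can be near-singular, so a diagonal shrinkage `shrinkage · trace/m`
  (default 1e−6) is added before factorization; with `shrinkage = 0` a
  singular fit raises an error that names the remedy.
* The empirical CDF uses `rank/(n+1)` at the order statistics with
  linear interpolation between them and exponential tails (scale = the
  margin's standard deviation) beyond the observed range, so the
  transform and its inverse are defined for all Gaussian scores; the
  round trip over the reference values is exact to interpolation
  tolerance.
* Reproducibility is contractual: the sampling variants refuse to run
  without a seed, and each subset's expectation derives its own seed
  from the model's base seed and the subset bitmask, so results do not
  depend on evaluation order and single expectations can be reproduced
  in isolation.

`compareToExact()` reports the mean square difference to the exact
values (overall and restricted to uniform instances) and a
symmetry-violation listing: pairs of features whose subset behavior is
exactly interchangeable in the table must receive equal exact values,
so any difference in an approximation is an axiom violation, which is
how approximation error manifests qualitatively.

## LIME surrogates

The LIME procedure standardizes each feature robustly in log space,
`z = (log x − median)/(IQR/1.35)`, draws `nPerClass` independent
standard-normal z-vectors per class (feature correlations deliberately
ignored), back-transforms them with *class-specific* medians and IQRs,
classifies every draw with the full-panel kNN, and discards draws whose
classification contradicts the class whose distribution generated them.
Kept draws are weighted by a Gaussian kernel on standardized Euclidean
distance to the explained instance, `w = exp(−d²/σ²)`, with σ equal to
the mean distance over kept draws for the logistic surrogate and half
that for the SVM surrogate; σ is recomputed per explained instance,
since the distances depend on the instance, and a multiplier is exposed
for boundary-region variants with tighter locality. The explanation is
the surrogate's coefficient vector on the standardized features.

Surrogate hyperparameters are deliberately minimal, because the
coefficients are the deliverable:

* The logistic surrogate uses a negligible ridge (1e−8, `ridge = 0`
  for a plain unpenalized fit). The discard rule makes the kept Good
  and Poor clouds disjoint across the kNN decision surface; when that
  surface is close to a hyperplane — the typical situation for cleanly
  separated classes — the clouds are linearly separable and the
  unpenalized maximum-likelihood estimate diverges. The tiny ridge
  keeps the optimum finite without materially changing coefficient
  ratios.
* The SVM surrogate is a weighted L2-regularized squared-hinge linear
  SVM at unit cost, with the proximity weights normalized to total
  one, fitted by L-BFGS-B with an analytic gradient. No installed SVM
  implementation accepts per-observation weights, so the package
  authors this fit directly; the squared hinge makes the objective
  differentiable, and the weight normalization makes the fit invariant
  to duplicating the training sample — only the weight *profile*
  matters. The explanation is the normal vector of the fitted decision
  plane.
* Labels are encoded Poor = 0 / Good = 1 for the logistic surrogate and
  −1/+1 for the SVM, so positive coefficients always push toward Good.

The permutation count defaults to 1e4 per class, which the test suite
uses throughout; the full-scale procedure (5e5 per class) is a
parameter away and changes cost, not code path.

## The synthetic cohort generator

No public feature table exists for the clinical test, so the generator
emulates the statistical structure such data exhibit, and its defaults
are fixed once:

* **Multivariate log-normal intensities** — Gaussian in log space,
  guaranteeing positivity and matching the log-space treatment used
  throughout. Per-class mean vectors and covariances are free
  parameters.
* **Composition** — reference sets of 13 Good / 13 Poor; cohorts of
  189 Good / 67 Poor instances with three technical replicates,
  mirroring the deployed test's design.
* **Correlation 0.6** (equicorrelated), inside the 0.31–0.996 range
  reported for panels of this kind, whose features are largely
  isoforms of one acute-phase protein.
* **Class separation 6 log units** along the equal-loading direction
  (all features shift together, as co-regulated proteins do). The
  equicorrelation concentrates within-class variance along exactly
  that direction (sd ≈ 1.14 log units at the defaults), so this
  corresponds to ≈5.3 within-class standard deviations: classes
  separated cleanly enough that reference sets are self-consistent and
  uniform instances exist, while the segment between the class
  centroids still crosses a genuine decision surface for the boundary
  constructor. Smaller separations emulate overlapping cohorts, and
  `separation = 0` exercises the self-consistency warning.
* **Replicate noise sd 0.05 log units** — i.i.d. Gaussian log-space
  noise, the simplest one-parameter model of technical replication.

What the generator does *not* emulate: heavy-tailed or skewed margins
beyond log-normality (stress-testing the copula against truly
non-Gaussian margins requires passing custom covariances or externally
generated tables), batch effects, censored/missing peaks, or any
relationship between feature values and clinical outcome. Passing
tests therefore demonstrate correctness of the explanation machinery
on data with the assumed structure, not fidelity of any approximation
on real clinical cohorts — on real data the published cohort-level
discrepancies between approximate and exact values cannot be
reproduced here and are not asserted anywhere in the package.

Uniform instances are constructed at the target class's reference
log-centroid and pushed deeper (away from the other centroid) until the
exhaustive subset table verifies uniformity; boundary instances are
found by bisection in log space between a Good- and a Poor-classified
point until the bracket is shorter than `tol` (default 1e−9 log units).
Truth metadata is returned separately from the feature table so
pipelines cannot accidentally leak generating labels.

## Problem sizes and determinism

The test suite runs at desk scale by choice: 1e4 permutations per class
for the LIME contracts, N ∈ {100, 1000} with 12 seeds for the
Monte-Carlo 1/N convergence check, 100-instance cohorts for the axiom
sweep, and n = 10,000 draws for covariance recovery. Every stochastic
path takes an explicit integer seed, and a (spec, seed) pair fully
determines every generator output, down to byte-identical CSV exports.

## Known limitations

* The exact machinery is exponential in the panel size; it is meant
  for small diagnostic panels (the permutation oracle refuses
  `m > 8`), not genome-scale classifiers.
* Interaction values for a binary classifier are exact but not very
  intuitive — for uniform instances they are negative while all
  features agree — and no normalization is invented to soften this.
* The LIME surrogates inherit the method's locality dilemma: instances
  deep in one class's region need permutations from both classes, so
  "local" necessarily stretches toward global, and a linear surrogate
  near the highly nonlinear kNN boundary is a rough approximation by
  construction.
* Kernel SHAP hybrids combine feature values never jointly observed;
  that is a property of the method being studied, reproduced
  faithfully, not corrected.
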