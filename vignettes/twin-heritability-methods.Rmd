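---
title: "Methods: twin variance components for static and dynamic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin variance components for static and dynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinconn)
```

## The model

A connectivity phenotype measured on both members of a twin pair is
modelled as bivariate normal with a single free mean shared across twins
and zygosities, and an exchangeable covariance whose diagonal is the
total variance and whose off-diagonal encodes twin resemblance:

* **ACE**: total a²+c²+e²; co-twin covariance a²+c² (MZ) or a²/2+c² (DZ).
* **ADE**: total a²+d²+e²; co-twin covariance a²+d² (MZ) or a²/2+d²/4 (DZ).
* **AE**, **E**: nested restrictions (c = 0, then a = 0).

Assumptions inherited from the classical twin design: equal environments
across zygosities, no assortative mating (DZ additive correlation fixed
at 0.5), no gene–environment interaction, and order-exchangeable twins
(the likelihood depends on twin order only through order-invariant
sums, so labelling within a pair is arbitrary). Phenotypes are
z-standardized cohort-wide before fitting, which makes the variance
components directly interpretable as fractions; the AE heritability is
a²/(a²+e²) × 100.

Parameters are optimized on the *path-coefficient* scale (a, c, e
unconstrained, variances their squares), so non-negativity of variance
components is structural, and boundary solutions (a² → 0 for null
edges) are reachable. The log-likelihood is evaluated from per-zygosity
sufficient statistics (sums, squares and cross-products), so a fit costs
the same for 16 pairs as for 40 000 and large calibration studies are
cheap.

### Numerical choices

* Optimizer: BFGS with `reltol = 1e-14`, multi-started from (i) a
  Falconer-derived point (a² ≈ 2(r_MZ − r_DZ), c² ≈ 2r_DZ − r_MZ,
  clipped into the interior), (ii) an equal split, (iii) an E-dominant
  point. The E model has a closed-form ML solution (grand mean, ML
  variance) that warm-starts AE; the AE solution warm-starts ACE/ADE
  with a near-zero shared path. This nesting chain makes
  logL(ACE) ≥ logL(AE) ≥ logL(E) hold numerically on every dataset, a
  property the test suite asserts.
* The genetic-effect test 2(logL_AE − logL_E) is referred to χ²(1) by
  default. Because a² = 0 sits on the parameter boundary, the asymptotic
  null is really the mixture ½χ²(0) + ½χ²(1); the χ²(1) reference is
  therefore *conservative* (measured type-I rate ≈ 2–3% at nominal 5%).
  The mixture reference is available via `boundary_mixture = TRUE` and is
  documented as less conservative.
* Model family: ADE iff r_MZ > 2·r_DZ, with the boundary going to ACE;
  intraclass correlations use the one-way ANOVA estimator
  (MSB − MSW)/(MSB + MSW), the standard twin-literature form with a
  hand-computable oracle.
* Edge tables report `a_effect` as the **AE model's** additive fraction
  for every edge, regardless of which model the AIC prefers. Reporting
  the chosen model's own A fraction instead would make a strongly
  heritable edge whose sampled r_DZ happens to fall below r_MZ/2 appear
  non-genetic (the ADE fit can reassign all genetic variance to
  dominance); the AE additive fraction absorbs narrow- and broad-sense
  genetic variance into one comparable number, which is also how the
  per-edge values are conventionally published. The AIC-selected model
  name is reported alongside.
* Multiple testing defaults to Bonferroni at α = 0.05 (flag: adjusted
  p < α); Benjamini–Hochberg and other α (e.g. 0.03) are configuration.
  The literature this package serves is ambiguous about whether such a
  threshold is the family-wise α or a corrected cutoff, so both are
  exposed rather than resolved.

## Connectivity phenotypes

* **Frames and blocks.** Frame indices are 0-based with frame *k* at
  time *k*·TR; block membership is half-open [onset, onset+duration).
  Boundary arithmetic uses a ceiling with 1 ns slack so that a block
  whose end falls exactly on a frame time does not gain or lose a frame
  to floating-point representation (30 frames at TR 0.72 s span exactly
  21.6 s).
* **Window parameters.** Default window 18 s and step 3 *frames*. At
  TR = 0.72 s the window is round(18/0.72) = 25 frames. The step is
  interpreted in frames (2.16 s) because steps are applied to the sampled
  series; a rectangular (boxcar) window with no taper is used. Windows
  are computed per block, never cross block boundaries, and are pooled
  across a condition's blocks and runs for the per-edge mean and
  unbiased (n−1) variance.
* **Standardization.** Each window's series is re-standardized within
  the window before correlating, so every window matrix is exactly the
  static Pearson matrix of its frame slice (asserted bit-for-bit in the
  tests). A zero-variance ROI over a *selected frame set* is a hard,
  named error; a zero-variance segment *within one window* drops that
  window with a logged count — one bad window should not void a subject.
* **Static method.** Pearson by default; a shrinkage-regularized partial
  correlation (covariance shrunk toward identity with a
  Ledoit–Wolf-style analytic intensity, then the standardized negated
  precision off-diagonal) is available behind `method = "partial"`. The
  source literature describes both for whole-brain static FC without
  resolving which was used where; both are provided, Pearson is the
  default, and the discrepancy is documented rather than resolved.
* **Contrast.** All genetic analyses run on the 2-back − 0-back
  differential phenotype, which removes perceptual/motor components
  common to both loads. An optional Fisher r-to-z transform applies
  `atanh` to staticFC and dfcMean only (dfcVar is not a correlation).

## Dynamic states

Window matrices are averaged within Yeo-7 network blocks; the feature
vector per window is the network matrix's 7 diagonal (within-network)
entries plus its 21 upper-triangle entries, z-scored over the pooled
(all subjects × all windows) sample. Including the diagonal is an
interpretation: the state contrasts of interest are within-network, which
requires within-network features. One k-means model (k = 2 by default,
k-means++ seeding, best of `n_init` restarts) is fitted across all
subjects' windows jointly; states are then relabelled by ascending
group-mean occupancy, so State 1 is always the transient state and the
labelling is independent of seeding. Dwell is the mean run length in
*windows* of the overlapping step-3 windowing, with no conversion to
seconds and no deduplication of overlapping windows; transition counts
are included as a third temporal metric because switching behaviour is a
distinct heritable-candidate trait. Within each subject, windows are
ordered run-by-run and block-by-block with the 0-back stack preceding
the 2-back stack; run and condition boundaries are treated as
consecutive for dwell purposes.

## What the synthetic cohort does and does not emulate

The generator provides ground truth at two levels.

*Phenotype level* (`simulate_ace_phenotypes`): exact ACE/ADE draws —
additive factors correlated 1.0/0.5 (MZ/DZ), dominance 1.0/0.25, one
shared C per pair, independent E — with unit marginal variance. This is
the level used for quantitative recovery claims, because it is exact:
r_MZ → a²+c² and r_DZ → a²/2+c² by construction.

*Time-series level* (`simulate_twin_timeseries`): zero-mean multivariate
normal frames whose correlation follows a frame-level Markov regime
(per-state stay probabilities, network-block correlation structure),
with per-subject, ACE-structured increments added to target edges during
2-back frames. Defaults mirror the study conditions: 134 MZ + 78 DZ
pairs on the generator, TR 0.72 s, two runs of eight 25-s task blocks
(2.5-s cues, interleaved fixation). Covariances broken by an increment
are repaired by eigenvalue clipping at 1e-6 and rescaling to unit
diagonal — the simplest positive-definite repair that preserves
structure — and increments beyond |r| = 0.99 are clipped with a warning.
Not emulated: hemodynamic-response convolution, 1/f noise and motion
artifacts, spatial maps, and any generative account of *how* heritable
signal physically enters BOLD. Passing end-to-end tests therefore shows
the pipeline recovers what it plants under idealized noise, not that
real BOLD obeys this generative model; quantitative recovery targets use
the phenotype-level generator only.

## Known limitations

* **Occupancy bias under fast switching.** With stay probability 0.9 the
  mean regime run (10 frames) is shorter than the 25-frame window, so
  most windows mix regimes. k-means then splits the window population
  asymmetrically whenever the two regimes differ in estimator noise
  (the sampling SD of a window correlation scales with 1 − r²): the
  recovered group occupancy deviates from the planted stationary 0.5 by
  roughly 0.08 under the default regime pair, at any ROI density. Regime
  *identity* is still recovered reliably — windows that are ≥ 90% one
  state cluster with adjusted Rand ≈ 0.95 when each network contributes
  at least a handful of ROIs. Mixed windows have no well-defined planted
  state, so label-agreement checks are evaluated on near-pure windows;
  occupancy checks use all windows.
* **Network feature noise at tiny parcellations.** With only 2 ROIs per
  network a within-network feature is a single 25-frame correlation
  (SE ≈ 0.2) and even pure windows misclassify at ~5%. State analyses
  need several ROIs per network; the 14-ROI pipeline default is a smoke
  scale, not a recommendation.
* **Test problem sizes.** The suite exercises recovery at 200 replicate
  cohorts of 134+78 pairs for heritability anchors, 500/200 replicates
  for LRT calibration/power, 20 000+20 000 pairs for ACE closed-form
  consistency, 20-subject cohorts of 500 frames for state recovery, and
  a 32-pair/14-ROI cohort for the end-to-end determinism check — sizes
  chosen so the full suite runs in a few minutes on one CPU while the
  Monte-Carlo error stays well inside each tolerance.
* The CE model, sex-limitation/age moderation, multivariate genetic
  models and extended pedigrees are out of scope, as are NIfTI/CIFTI
  parsing and fMRI preprocessing (inputs are parcellated text
  matrices; a converter hook is the natural extension point).
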