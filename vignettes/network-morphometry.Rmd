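---
title: "Methods: network-guided morphometry analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-guided morphometry analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmorph)
```

## Overview

`netmorph` analyses participants × vertices matrices of cortical thickness
(mm) and surface area (mm²), organised by a 7-network functional
parcellation, in four stages: composite cognitive scores, cross-validated
select–average–regress prediction per network, bootstrap inference with
difference-of-coefficients mediation, and vertex-wise bootstrap-ratio (BSR)
maps with a permutation enrichment test. This vignette documents the models
and their assumptions, the tunable parameters, the synthetic-data generator
that serves as the package's testbed, numerical conventions, and known
limitations.

## Composite cognitive scores

Eleven task scores are winsorized at ±3 SD of each task's own mean/SD in a
single pass (boundaries are not re-estimated after replacement). Tasks where
lower raw values mean better performance — response times, completion times,
error counts — are multiplied by −1 *after* winsorization and *before*
standardization; without this step the loading matrix of a two-block battery
cannot be uniformly positive and the composites would have no common
direction. The orientation step is a modelling commitment of this package:
the analysis it reimplements leaves it implicit, but it is forced by the
positivity of the published rotated loadings.

The direction-corrected battery is z-scored and decomposed by PCA; the first
two components are retained (a fixed count, not an automatic scree-inflexion
detector) and varimax-rotated with Kaiser normalization (`stats::varimax`,
convergence tolerance 1e-6). Because an orthogonal rotation is identified
only up to sign and permutation, signs are fixed so each component's
dominant task loads positively, and components are ordered by post-rotation
variance explained. Each task is assigned to the component with the larger
absolute loading; each composite is the mean of its member tasks' z-scores,
so composites have mean zero and "higher = better" by construction.

Two numerical caveats are worth recording. First, a *perfectly* symmetric
two-block battery (equal-size blocks of noise-free indicators) sits at a
stationary point of the Kaiser-normalized varimax criterion where no
rotation improves simplicity; any asymmetry (the package's 6-vs-5 default
battery is asymmetric) removes the degeneracy. Second, PCA loadings estimate
the varimax rotation of the first two principal components of the
population correlation matrix, which is *not* the generating factor-loading
matrix when indicators carry unique variance; the package's tests therefore
compare sample solutions against the closed-form population PCA+varimax
oracle rather than against the generating loadings.

## Select–average–regress prediction

For a network's matrix (vertices restricted via `subset_network()`; network
`"whole"` keeps codes 1–7 and drops the unlabeled medial wall), a repeated
k-fold cross-validation (defaults: k = 5, 100 iterations; the package's
tests and examples use 10 iterations) proceeds per training fold:

1. **Robust scaling.** Each vertex is centered on its training-fold median
   and divided by its training-fold IQR (25th–75th percentile,
   linear-interpolation quantiles, `type = 7` — the dominant convention,
   fixed here so results are reproducible). Zero-IQR vertices are centered
   and divided by 1 rather than dropped: near-constant vertices occur in
   masked cortical data and silently removing them would change the
   per-network vertex counts that downstream stages report.
2. **Univariate selection.** Each scaled vertex's two-sided
   correlation-test p-value against ability (t with n−2 df) is compared to
   a threshold α; the default ladder is .05, .01, .001, .0005, .0001. These
   are raw p-value thresholds, not FDR-corrected levels.
3. **One-coefficient model.** The selected vertices are averaged per
   participant and ability is regressed on the single mean by OLS.
4. **Prediction.** Held-out rows are scaled with the *training* parameters,
   masked with the *training* selection, and pushed through the training
   model. Scaling, selection, and fitting never see test rows.

A fold where no vertex survives an α contributes no predictions at that α;
this is recorded in the diagnostics (fraction of empty folds per α), never
raised as an error, and a participant's α-level prediction is the mean over
the iterations in which one was produced. The across-α average — the
quantity used for inference — averages the per-α participant means over the
α at which the participant received any prediction. (An alternative reading
would pool all fold-level predictions before averaging; with equal fold
counts the two coincide, and the per-α-then-across-α order is adopted
because inference is explicitly drawn from the five per-threshold
predictions.)

Fold partitions are uniformly random with near-equal sizes, unstratified.
Iteration *i* uses a sub-seed derived deterministically from the master
seed, so increasing the iteration count never changes earlier folds.
Per-fold slopes and selection counts are exported: a slope distribution
that straddles zero across folds flags an unreliable (worse-than-chance)
model, which is diagnostic rather than an error.

## Bootstrap inference and mediation

All inference uses a case (pairs) bootstrap: rows are resampled with
replacement so that ability, predictions, age, and covariates stay paired,
and the statistic — including any internal residualization or
re-standardization — is recomputed per resample (default B = 5000; scaled
runs use 200–1000). Reported are the percentile 95% interval (2.5/97.5) and
additionally the 90% (5/95) interval, since interval-width phrasing in this
literature is sometimes ambiguous; the 95% interval is the one the package
treats as primary. Significance is the one-sided `p_boot` = proportion of
draws ≤ 0, matching a "proportion of coefficients greater than zero"
criterion for positive alternatives; a two-sided p would double small
values. The plain proportion is reported without a +1 correction, so
p = 0 is representable with resolution 1/B.

The mediation model fits `ability ~ age + sex` and
`ability ~ age + mediator + sex` by OLS and takes the drop in the age
coefficient as the mediation effect. Age is negated before fitting so
age-driven decline carries a positive sign; age, mediator, and ability are
standardized so coefficients are commensurate with correlations, while
binary sex is left as coded. For linear models the difference of
coefficients equals the product of the age→mediator and mediator→ability
paths exactly — the package keeps this identity as a standing regression
test at machine precision.

## Vertex-wise BSR maps and permutation enrichment

For every vertex, the sex-adjusted partial correlation with ability (or the
per-vertex mediation effect, with the observed vertex value as mediator) is
bootstrapped and summarized as BSR = mean(draws)/SD(draws), treated as
approximately standard normal. One set of B resample index vectors is drawn
per map and reused across all vertices — the resampling scheme is not
vertex-specific in any case, and sharing makes a cortex-wide map a handful
of matrix products per resample. Vertices with (near-)zero bootstrap SD or
zero variance are flagged undefined and excluded from all counts.

Suprathreshold vertices are counted per network at thresholds 1.96, 2.58,
3.3, 3.9 (two-sided normal p of .05, .01, .001, .0001). Counts use the
positive tail (BSR ≥ t) by default, since the substantive hypotheses
concern positive structure–cognition effects; an absolute-value variant is
available because either convention is defensible. The enrichment null
shuffles BSR values across all labeled, defined vertices (implemented as a
label permutation, which is distributionally identical) and recounts;
`p_ge` is the proportion of permutations with a count at least the
empirical one, and `p_le` (at most) supports "fewer than chance" claims.
Under this null each network's count is hypergeometric with mean
(network size / labeled total) × whole-map count — the package's tests
check the permutation machinery against that closed form and against
exhaustive enumeration on tiny maps.

## The synthetic-cohort generator

`simulate_cohort()` is the package's testbed: it generates cohorts with the
statistical structure the analysis assumes, so every downstream stage is
testable without data. The default configuration encodes the study
conditions the package targets — 165 participants (105 female), ages 60–89
with mean 69.5 and SD 6.58, global mean thickness 2.39 mm (cohort SD
0.12 mm), total surface area 157,614 mm² (SD 15,776 mm²), an 11-task
battery with a 6-task executive and 5-task episodic-memory block, and
factor–age correlations of −0.30 and −0.36.

The generative model:

* **Age** is a truncated normal on [60, 89]. The underlying (pre-truncation)
  mean and SD are moment-matched numerically so that the *truncated*
  distribution has the configured mean/SD — naively truncating
  N(69.5, 6.58²) would shift the mean up by ~1 year and shrink the SD to
  ~5.7, missing the configured moments.
* **Latent factors.** Two unit-variance factors with configured mutual
  correlation (default 0.35, a realistic executive–memory association) and
  configured correlations with standardized age.
* **Tasks** are loadings × factors + Gaussian noise, with per-task noise SD
  chosen so each indicator has approximately unit variance. All synthetic
  tasks are generated higher-is-better; direction handling is exercised in
  the composites module, not here.
* **Vertices.** Each vertex carries a baseline, an additive sex effect on
  thickness and a multiplicative one on area (females thicker cortex,
  smaller area), a participant-level global component, a network-specific
  linear signal in (factor 1, factor 2, −standardized age), and spatially
  smoothed noise. Smoothing is a moving average over the 1-D vertex index
  within each network (half-width 5 by default), rescaled to preserve unit
  variance: the only property downstream code is sensitive to is that
  neighboring vertices are correlated, so no mesh geometry is modeled.
* **Cluster structure.** Each network's effect is carried by a contiguous
  cluster covering a fraction (default 0.4) of its vertices at amplitude
  coupling/fraction, so the *network-average* coupling equals the
  configured value while individual cluster vertices carry a signal the
  p-threshold selection step can actually find — mirroring real cortical
  effect maps, where a minority-to-half of vertices are suprathreshold
  rather than the whole network being uniformly associated.
* **Calibration.** The default coupling matrix was set so the *emergent*
  cohort-level correlations of global mean thickness with the two abilities
  and with age land near 0.25 / 0.26 / −0.32 at the default cohort size,
  and area–cognition couplings are zero. The variance of the participant
  global component is reduced by the variance already induced by the mean
  network signals and the sex effect, so the configured global-moment SDs
  are recovered. Cross-measure (thickness–area) coupling is left at zero:
  the empirical vertex-level association is only loosely characterized
  ("weaker, negative"), and a guessed value would be harder to defend than
  an explicit zero.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: mesh geometry and true 2-D smoothing
kernels, reconstruction error and manual-edit effects, heavy-tailed or
missing behavioral scores, site/scanner effects, and thickness–area
covariance. One structural difference deserves emphasis: in the generator,
cognition and the coupled vertices *share a latent factor*, so a
morphometry-based prediction can proxy the outcome's direct cause and the
synthetic mediation effects are stronger (sometimes exceeding the total
effect, with a negative direct effect) than in typical observational
cohorts, where all mediation paths run through age-related processes.
Synthetic results calibrate the machinery; they are not effect-size
forecasts.

## Problem sizes and determinism

The tests and the bundled acceptance script run at scaled sizes chosen as a
deliberate design point: 2,000 vertices (the generator's stand-in for a
~300k-vertex cortex), 10 CV iterations, B = 200–1000 bootstrap resamples,
and 2,000 permutations; full-scale settings (100 iterations, B = 5000,
100,000 permutations) are plain arguments. Every stochastic stage takes an
explicit integer seed, fixed-seed runs are bit-reproducible, and
`run_study()` writes an MD5-checksummed manifest so reruns can be verified.
Surface matrices are written to CSV with 17 significant digits so a
write-then-read round trip reproduces the doubles exactly.

## Known limitations

* Vertex selection uses raw p-value thresholds by design; no multiplicity
  correction is applied or intended at the selection stage.
* The permutation null treats vertices as exchangeable units; spatial
  autocorrelation makes the effective number of independent units smaller,
  so enrichment p-values on smooth maps are anti-conservative relative to a
  cluster-aware null. The same caveat applies to the published procedure
  this package reimplements.
* The one-coefficient average model deliberately ignores the sign pattern
  of selected vertices; batteries of mixed positive/negative effects
  produce unstable fold slopes (visible in the exported diagnostics) rather
  than better fits.
* `cohort_composites()` labels components via a majority vote of a
  configurable executive task set; for non-default batteries the caller
  should pass `executive_tasks` or work with `pca_varimax()` directly.
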