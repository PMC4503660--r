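---
title: "Methods: maximum-entropy climatic suitability modelling with climaxent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy climatic suitability modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical method it
implements, the conventions it fixes where more than one reading is
defensible, and what its synthetic validation does and does not establish.

## The model

`climaxent` models presence-only species records with the maximum-entropy
(Gibbs) formulation: over the fitting cell set, the probability that a
randomly drawn presence falls in cell $x$ is

$$P(x) = \frac{\exp\big(\sum_j c_j f_j(x)\big)}{Z},$$

where the $f_j$ are feature transforms of the bioclimatic covariates and
$Z$ normalizes $P$ to a distribution. This is the distribution of maximum
entropy among those matching the presence sample's feature expectations,
and equivalently the exponential-family model maximizing the presence
likelihood. The method presumes (i) the species is in equilibrium with the
covariates, (ii) the occurrence sample is drawn (roughly) proportionally to
suitability, and (iii) the background sample characterizes the available
environment. None of these can be verified from presence data alone; the
synthetic generator exists precisely to create worlds where they hold by
construction, so estimator failures cannot be blamed on assumption
violations.

### Features and normalization

Each covariate is min-max normalized to $[0,1]$ using its *background*
extremes; prediction-time values outside that range are clamped (the usual
"clamping" convention, keeping features bounded under mild novelty). On
the normalized scale:

* *linear* — the value itself; *quadratic* — its square;
* *product* — pairwise products of distinct variables (squares are already
  covered by quadratic features);
* *threshold* — a step, 1 strictly above a knot $v$;
* *hinge* — 0 at or below $v$, rising linearly to 1 at the background
  maximum.

Knots sit at $v = i/(k+1)$, $i = 1..k$, with $k = 10$ per kind by default —
enough resolution for landscape-scale response shapes while keeping the
feature count (364 for 13 variables) small relative to a 10,000-cell
background. Covariates constant over the background carry no information
and are dropped with a warning.

### Regularization

The fit minimizes

$$J(c) = \log Z(c) - \overline{\eta}_{\text{presence}}
  + \sum_j \lambda_j |c_j|,\qquad
  \lambda_j = \beta\,\frac{\mathrm{sd}_{\text{bg}}(f_j)}{\sqrt{m}},$$

with $m$ the presence count. Scaling $\lambda$ by the feature's background
standard deviation penalizes informative directions in proportion to their
leverage, and the $1/\sqrt{m}$ factor lets the penalty vanish at the rate
statistical error does. The global multiplier $\beta$ defaults to 1 (and
may be set per feature kind); the original MaxEnt's empirically tuned,
sample-size-dependent $\beta$ tables are deliberately out of scope — one
transparent rule, stated here, rather than an opaque lookup.

### Optimizer and numerics

Coefficients are fitted by cyclic coordinate descent in compiled code:
each coordinate takes a proximal-Newton step (a soft-thresholded
second-order step using the current cell distribution's mean and variance
of that feature), safeguarded by backtracking line search on the true
objective, so the objective decreases monotonically. After each full sweep
the active (non-zero) set is iterated until it stops improving — the
standard acceleration for L1 paths. One *iteration* is one sweep;
fitting stops when a sweep improves the regularized objective by less than
`tol` ($10^{-5}$ by default) or after `max_iter` (500) sweeps. Log-sum-exp
is always computed with max-subtraction; feature variances are floored at
$10^{-12}$ and background feature standard deviations at $10^{-6}$ inside
$\lambda_j$ so that degenerate features cannot produce unbounded steps.
On toy problems with up to three features the fitted objective matches a
dense grid search to $10^{-12}$ (the test suite asserts $10^{-4}$).

The fitting cell set is the background sample plus any presence cells not
already in it; $Z$, the training gain and the entropy $H$ all refer to
that set, and the fitted raw distribution sums to 1 over it to $10^{-9}$.

Two gain scales coexist, deliberately:

* `training_gain()` — $\log N$ minus the mean negative log raw probability
  of presences (0 for the uniform model); the quantity usually read off
  MaxEnt output.
* the model's `reg_gain` — $\log N$ minus the *optimal penalized*
  objective. Only on this scale is "a feature subset can never out-gain
  its superset" an exact theorem, so the jackknife importance columns use
  it; the unpenalized gain at a regularized optimum can exceed a
  superset's by the difference in penalties.

### Logistic output

The 0–1 suitability index is $e^H P(x)/(1 + e^H P(x))$ with $H$ the
entropy of the fitted raw distribution: a monotone rescaling under which a
"typical" cell ($P = e^{-H}$) scores 0.5, and the uniform (null) model
scores 0.5 everywhere.

## Evaluation

ROC/AUC treats the background sample as the contrast class
("pseudo-absences"), computed exactly in Mann-Whitney form with half
credit for ties — equal to trapezoidal integration of the threshold-swept
curve, and to brute-force pair counting (asserted to $10^{-12}$). AUC
bands follow the conventional five-band scale, half-open with the top band
closed, so 0.70 reads "good" and 1.0 "excellent". k-fold cross-validation
(default $k = 10$) deals a seeded permutation round-robin, fits on $k-1$
folds, and scores the held-out presences against one *shared* background
sample — the per-fold background alternative is not implemented, since
varying the negative set across folds confounds fold variance with
background sampling variance. The per-fold logistic maps are combined
cell-wise with test-AUC weights.

## Importance and response curves

Percent contribution credits every accepted coordinate update's objective
decrease to the updated feature's source variable (product features split
half and half). It is a path-dependent heuristic — reordering the
coordinate sweeps could shift it — which is why the jackknife columns
(refit with only / without each variable) accompany it; on the synthetic
fixture both agree on the truth's driving variables. Response curves refit
the model with a single variable to avoid correlated-covariate artifacts,
then evaluate the logistic output on an even grid over the background
range.

## MESS and limiting factors

With $f$ the percent of reference (presence) values strictly below the
probe, similarity is $2f$ (or $2(100-f)$ above the median), and beyond the
reference extremes it goes negative in proportion to the overshoot scaled
by the reference range. Both boundary branches carry the $\times 100$
range scaling: printed forms of this rule sometimes carry the factor only
on the upper branch, which would make the surface discontinuous at the
reference minimum; `eq2_literal = TRUE` reproduces that asymmetric form
for comparison. Because the percentile is *strictly* "smaller than", a
probe equal to the reference minimum scores exactly 0, and a probe at the
middle value of an odd-sized reference has $f < 50$ (e.g. $f = 40$, score
80, for the middle of five) — only probes with exactly half the reference
strictly below score 100. The multivariate surface takes the per-cell
minimum across variables; the argmin is the cell's limiting variable, with
ties broken by the canonical layer order for determinism. Negative
similarity is equivalent to being outside some variable's reference range,
cell by cell.

## Bioclimatic indices

Thirteen layers are derived per cell from 12 monthly values; a cell
missing any month is missing in all layers. Three conventions have two
defensible readings, so each is a mode with a fixed default:

* `art_mode` — "annual range of temperature" defaults to max monthly
  maximum minus min monthly minimum (`annual_range`); the alternative
  `footnote_literal` (mean monthly diurnal range) is retained, but annual
  ranges of tens of degrees in temperate habitats are only reachable under
  the default.
* `psd_mode` — precipitation seasonality defaults to the plain coefficient
  of variation, $100\,\mathrm{sd}/\mathrm{mean}$ (population sd: the 12
  months are the whole climatology, not a sample; 0 when the mean is 0);
  `worldclim_cv` adds 1 to the mean as WorldClim does. PSD is labelled %
  — reports quoting it in mm conflate it with its numerator.
* `abt_mode` — annual biotemperature defaults to Holdridge's clamp of
  monthly means into $[0, 30]$ °C; the literal alternative sums only
  months strictly inside $(0, 30)$. The two agree except where months sit
  at or beyond the bounds.

Kira's indices use strict inequalities: months at exactly 5 °C contribute
to neither warmth nor coldness. The potential evapotranspiration ratio
$58.93\,\mathrm{ABT}/\mathrm{AP}$ is dimensionless in substance (its
occasionally printed °C/mm unit is cosmetic); it and the humidity index
$\mathrm{AP}/\mathrm{WI}$ are undefined (NoData) at zero denominators.

## Habitat classes, envelopes, areas

Logistic suitability is binned at 0.25 / 0.5 / 0.75 into unsuitable,
marginal, moderate and core — half-open bins, top bin closed, so 0.75 is
core; the cut points are configurable. Envelopes report each class's
min-max per variable over member cells (verified against exhaustive
scans); envelope nesting across classes is an empirical pattern, not a
theorem, and is not asserted. Areas use the spherical approximation
$R^2\,\Delta^2 \cos\phi$ per cell ($R = 6371$ km, $\Delta$ the cell size
in radians, $\phi$ the cell-center latitude) — adequate at the cell sizes
involved and closed-form checkable, unlike a GIS zonal computation.

## The synthetic landscape and what passing tests mean

`generate_monthly_climate()` emulates the *structure* of interpolated
climatologies: a latitudinal temperature gradient with a seasonal
sinusoid, strictly positive seasonal diurnal half-ranges, a longitudinal
precipitation gradient with a summer-peaked profile, and spatially
autocorrelated noise (separable moving average — deterministic and
dependency-light, rather than spectral synthesis). Defaults: 100×100
cells at 10 arc-min, temperatures spanning roughly −3 to 36 °C across
season and latitude, annual precipitation roughly 150–1300 mm. It does
*not* emulate topography, rain shadows, monsoon dynamics, spatial sampling
bias, or coordinate error; passing recovery tests therefore demonstrates
estimator correctness under the model's assumptions, not robustness to
the violations real herbarium data exhibit.

The ground truth is itself a Gibbs surface: unimodal in annual
precipitation (coefficients 24, −24 on the normalized scale; optimum at
mid-range) with exponential decay in driest-month precipitation (−16).
These strengths were fixed once, by computing the truth's own
discriminability ceiling — the population AUC of scoring cells by the true
surface, ≈ 0.92 on the default landscape, in line with what strong
climate-envelope studies report — so that recovery checks (test AUC above
0.8, importance ranking) are decidable properties of the construction
rather than marginal outcomes. Occurrences are sampled from the *raw*
distribution (that is exactly what the estimator estimates, making
recovery well-posed), with replacement, at cell centers; n = 100 by
default.

Parameter recovery fits the matching family — linear + quadratic features
on the two truth variables, n = 500 presences, the full 10,000-cell
background — and measures total-variation distance to the truth. It uses
$\beta = 0.1$: with 4 features and 500 presences the default $\beta = 1$
penalty shrinks coefficients by roughly a third, a bias a practitioner
would not accept in a 4-parameter fit (measured TV ≈ 0.17 at $\beta = 1$
versus ≈ 0.04 at $\beta = 0.1$ and ≈ 0.02 unpenalized). Light
regularization is retained rather than none because the fitted object
should remain the package's regularized estimator, not a special case.

## Determinism and problem sizes

Every stochastic function takes an integer seed and restores the caller's
RNG state; `run_pipeline()` fans one master seed out to stages at fixed
offsets, and two runs with the same inputs and seed are byte-identical
(asserted over file hashes). The test suite and the reproduction script
run at the fixture's native sizes — 100×100 cells, 10,000 background
points, 100 occurrences, 10 folds, 500-presence recovery draws — chosen as
the smallest scale at which all of the paper-style workflow's moving parts
(cross-validation variance, importance separation, MESS structure) are
clearly expressed.

## Known limitations

* Background normalization + clamping means predictions far outside the
  background range saturate; consult the MESS map before trusting them.
* Percent contribution inherits the optimizer's path dependence; prefer
  the jackknife columns for inference.
* The original MaxEnt's per-kind $\beta$ tables, cumulative output,
  bias grids and spatial thinning (beyond one-per-cell deduplication) are
  out of scope, as are reprojection and resampling — all layers must share
  one grid.
* AUC on presence-background data is a relative ranking measure; its
  absolute value depends on the background extent and should not be read
  as a probability of correct classification.
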