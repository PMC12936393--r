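---
title: "Telemetry-based habitat suitability modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telemetry-based habitat suitability modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`habtrack` implements a complete telemetry-to-habitat-model workflow for
marine megafauna foraging studies: satellite-tag fixes are quality
controlled, regularized with a continuous-time movement model, contrasted
against correlated-random-walk (CRW) pseudo-absences, annotated with
environmental predictors in space and time, and modelled with boosted
regression trees (BRT) under monotone constraints; the fitted model is then
projected onto a grid to map suitable habitat, quantify its area, its
change between dates, and its overlap with management zones.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions,
writing their tables under `results/`. Every computational step lives in
the package itself, where it is unit tested.

Because real tracking data and regional environmental servers are not
required, the package ships a seeded synthetic-data generator that emulates
a coastal study system with a known ground-truth suitability surface. All
statements below about recovery and accuracy refer to quantities the test
suite and `scripts/acceptance.R` actually compute on those synthetic
scenes.

# The synthetic study system

`build_scene(seed, n_rows, n_cols, n_dates)` generates, on one planar
metric grid (500 m pixels by default):

* a connected landmass along the western edge with a smoothly meandering
  coastline; the land mask stands in for the high-tide line;
* 6–8 elliptical reef patches at staggered distances offshore (staggering
  keeps distance-to-reef and distance-to-coast from being collinear);
* point facilities (boat-ramp analogues) and river mouths on the coast;
* a mangrove canopy-cover fringe (percent cover, used through the
  "at least 20% canopy" distance rule);
* exact Euclidean distance grids to reefs, coast, facilities and rivers;
* a seagrass probability field and a small-integer categorical geohabitat
  layer;
* dynamic monthly stacks of temperature, salinity and current speed.

Dynamic fields are band-limited Gaussian random fields evolving as AR(1)
in time. Their parameterisation encodes three deliberate design choices:

* **Temperature** varies mostly seasonally (austral summer warm), with a
  very smooth, small-amplitude spatial component (0.6 °C, decorrelation
  tens of km). Sea-surface temperature in an inshore domain carries little
  pixel-scale spatial contrast at a fixed date; letting it fluctuate at
  reef scale would make it a strong chance confounder of any spatially
  clustered usage pattern.
* **Salinity** combines a mid-scale stochastic field (1.2 PSU) with river
  flood plumes that strengthen in the wet season. Seasonal plume dynamics
  matter: a time-constant plume makes the static distance-to-river grid a
  perfect proxy for salinity, and the model could then explain a salinity
  preference without ever touching the salinity layer.
* Distances are exact centre-to-centre Euclidean transforms
  (Felzenszwalb–Huttenlocher two-pass algorithm), verified in the tests
  against an exhaustive per-pixel scan.

## Ground truth and movement

The truth model is a logistic suitability surface,
`plogis(intercept + sum_k f_k(x_k))`, with closed-form effects. The default
truth is driven by exactly two predictors: a strong monotone preference for
water near reefs (−1.6 logit per km of reef distance) and a comparably
strong unimodal salinity preference centred at the typical offshore
salinity (33.5 PSU, 1 PSU tolerance). Both effect sizes were chosen once so
that each driver contributes materially to acceptance probability at the
scales the animals experience; a driver too weak to shape movement would
make "recover the truth predictors" an ill-posed exercise.

Tracks are biased CRWs: gamma step lengths (mean 600 m per 2-h step) and
wrapped-Cauchy turning angles (concentration 0.7), with candidate steps
accepted with probability equal to the truth suitability at the candidate
and re-drawn when rejected or on land. Under a flat truth the realised
kernel therefore equals the proposal kernel exactly, which the tests verify
(mean step length, Kuiper test on turning angles). The true inter-fix
interval is 2 h, so 12-h regularization is a genuine down-sampling. The
default problem size (15 animals × 300 steps ≈ 25 days each) is the
package's study condition — desk-scale relative to months-long real
deployments, and every reported quantity is computed at this size.

## Telemetry degradation

`degrade_telemetry()` thins fixes by independent retention (default 0.45),
assigns each fix Fastloc GPS (70%) or an ARGOS class, and adds isotropic
circular-normal error per class. The GPS per-axis sigma is set so the mean
radial (Rayleigh) error is exactly 40 m; ARGOS classes 3/2/1 use 250 m /
500 m / 1.5 km mean radial error, and the low-quality classes 0/A/B (3, 5,
10 km) are generated only to be removed by QC. Exact duplicate rows,
empty rows, shuffled row order, and — for flagged animals — a directed
departure segment longer than 150 km are injected. True coordinates ride
along in `true_x`/`true_y` for validation; QC never reads them. Real tag
duty-cycles are unknown, so the retention model is a stand-in, not a claim
about any particular tag.

# Quality control

`qc_pipeline()` composes the filters in a fixed order, logging removal
counts so that input rows always equal output rows plus removals:

1. **Basic cleaning** — empty rows, exact duplicates, ARGOS classes other
   than 1/2/3 (GPS always kept), and the first 24 h after release. The
   burn-in anchors on a release time (default: the animal's first fix);
   passing the recorded anchors back makes the pipeline idempotent on its
   own output, which the tests assert.
2. **Speed/angle filter** — the published filters expose thresholds
   (9.9 km/h, 90° inner angle) but not an algorithm, so the package defines
   one: a fix is a violator when both adjacent legs exceed the maximum
   speed (endpoints: their single leg), or when it forms an inner angle
   under 90° with both legs above half the maximum speed. Violators are
   removed worst-first (largest minimum adjacent-leg speed) and the rules
   iterate to a fixed point. This concrete rule is an approximation to the
   cited filters, and is exercised against injected spikes: all >30 km/h
   spikes removed, under 1% collateral damage.
3. **Terrestrial filter** — fixes on land-mask pixels are dropped by pixel
   containment (half-open cells, so boundary points are deterministic).
4. **Splitting and trimming** — tracks split at gaps strictly over 72 h;
   only segments with strictly more than 20 fixes survive. Both
   inequalities are strict by the wording of the rules.
5. **Migration removal** — a departure is any fix beyond 150 km from the
   track start. The excursion is bounded by an onset (last fix within
   10 km of the pre-departure centroid) and, if the animal returns, a
   re-entry; the excursion interior is removed and the remainder re-split,
   so a post-return residency survives only as its own adequate segment.
   Truncation (rather than dropping the animal) is the default because it
   preserves foraging data; `migration_mode = "drop_track"` is available.
   The automated onset rule replaces visual identification of the end of
   directed travel and is necessarily a proxy.

# Regularization: CTCRW instead of move persistence

Error-corrected positions at regular timesteps come from a continuous-time
correlated random walk — an integrated Ornstein–Uhlenbeck velocity process
with reversion rate `beta` (h⁻¹) and diffusion `sigma` (m·h^(−3/2)) — fitted
per track by maximum likelihood through a Kalman filter over the irregular
intervals, with known isotropic per-class observation error. This is a
deliberate substitution for time-varying move-persistence models: the role
the model plays here is error correction and interpolation, and the CTCRW
version of that role has an exact finite-dimensional Gaussian oracle
(the dense joint-covariance conditional), which the tests exploit to verify
the smoother to 1e−6 relative error. The cost is that no behavioural
persistence parameter is estimated; that is listed as out of scope.

Numerical choices: optimisation is bounded L-BFGS-B on log-parameters from
three deterministic scale-aware starts, best likelihood wins; a fit is
declared converged only when the optimiser reports success, both
parameters are interior, and the numerical gradient is small relative to
the objective; tracks with fewer than 10 usable fixes are discarded
outright. The smoother runs over the union of observation times and the
regular grid, so estimates and their standard errors come from the same
pass.

Timestep selection automates what is usually a visual check. For each track
the candidate steps 12, 24, 48 h are tried in order and the first one
passing all diagnostics wins: per-axis lag-1 autocorrelation of
standardised one-step residuals below 0.3; non-degenerate output (circular
variance of estimated headings at least 0.01 — rejecting straight lines and
perfect loops); and no estimate farther than 5 stationary one-step
process SDs from both temporal neighbours. All thresholds are arguments.
Because the CTCRW parameters do not depend on the output timestep, one fit
serves all three candidates; the candidates differ in their interpolated
output and its diagnostics.

# Pseudo-absences

Each regularized track contributes empirical step lengths (successive
displacement norms) and turning angles (signed heading changes; angles at
zero-length steps are undefined and skipped with a count). A pseudo-absence
track starts at the source track's first estimated position with uniform
heading and, at each of the source timestamps, independently resamples one
step and one angle with replacement; candidates on land are redrawn up to
100 times, after which the heading reflects by π; as a final fallback the
walker stays in place for one step (its current position is at sea), so no
simulated point is ever on land — a hard assertion in the tests. Steps and
angles are resampled independently rather than jointly; the empirical
marginals are preserved exactly, step–turn dependence is not.

Nine simulations per presence track is the default contrast ratio,
matching the roughly 9:1 pooled absence:presence ratio implied by published
pooled totals in comparable workflows; the count is an argument. Per-sim
seeds derive deterministically from the master seed and the track and sim
indices.

# Annotation, screening, separation

Annotation is pure lookup, asserted bit-for-bit reproducible: static layers
by pixel containment; dynamic layers at the nearest stack date **not
after** the point's timestamp (model output is step-valid in time;
interpolating would invent values); categorical layers return integer
codes; points outside the grid or before the first dynamic date keep their
row with explicit missingness — nothing is imputed, and rows with missing
retained predictors are dropped (with counts) only at fitting time.

Temporal clipping removes presences and pseudo-absences alike outside the
dynamic coverage window and logs tracks that vanish entirely. Because
matched absences share the presence timestamps, clipping preserves count
parity.

The collinearity screen computes Pearson correlations over all labelled
rows (presences and absences; using both is the package's reading of an
underspecified choice) and, while any pair exceeds |r| = 0.70 strictly,
drops from the worst pair the member with the larger mean absolute
correlation to everything else (ties: later column order). The full
correlation matrix and every drop, with its triggering partner, are
returned for audit. Categorical predictors are exempt.

Environmental separation between presences and absences is scored with
Bhattacharyya's coefficient on 100 equal-width bins spanning the pooled
range (bin count is an argument; the coefficient is exact for the binned
distributions). The tests verify the Gaussian closed form
`BC = exp(−Δμ²/8)` to 0.02.

# The BRT engine

The boosting engine is written from scratch (C++ core) because it is the
analytical heart of the workflow: stagewise gradient boosting of
regression trees on the Bernoulli deviance.

* **Initialisation** at `logit(mean(y))`.
* **Per iteration**: draw a bag (75% of rows, without replacement, own
  deterministic RNG — results are bit-reproducible given the seed and
  independent of R's RNG state); fit a tree to the gradient residuals
  `z = y − p` by best-first growth to at most `tree_complexity` splits
  (default 5, i.e. at most 6 terminal nodes), choosing each split to
  maximise the squared-error gain; apply one-step Newton terminal values
  `Σz / Σp(1−p)` shrunk by the learning rate (default 0.005).
* **Monotone constraints** are enforced in two coupled ways: a split on a
  constrained numeric predictor is rejected when the ordering of its child
  Newton values violates the declared sign, and every node carries value
  bounds — tightened to the child-value midpoint at each constrained
  split, inherited by all descendants — into which terminal values are
  clipped. Sign checks alone do not bound what deeper sibling subtrees can
  do, so the bound propagation is what makes the guarantee global.
  Constraints on categorical predictors are ignored (meaningless over
  codes). The tests assert the resulting partial-dependence curves are
  monotone everywhere on a 100-point grid.
* **Categorical splits** by exhaustive subset search up to 8 levels, above
  that by ordering levels on within-node mean response; unseen codes at
  prediction time are routed through the majority branch with a warning.
* **Relative influence** credits each split's gain to its predictor and
  normalises to 100. Predictors above `100/p` are flagged influential.
* **Partial dependence** is the brute-force definition — the mean
  link-scale prediction over the training rows with the predictor
  overridden — computed in a batched C++ pass. The count-weighted
  tree-recursion shortcut is deliberately not used: it is inexact under
  splits on the target variable, and the tests demand 1e−9 agreement with
  the override definition. Two-way interaction strength is the residual
  variance of the 20×20-knot two-way PD surface around its best additive
  (row + column means) approximation, scaled by the surface variance.
* **Cross-validation** uses five seeded label-stratified folds at row
  level (fold-by-animal is a natural extension point; row level mirrors
  the common practice this workflow reproduces). **Pruning** removes a
  predictor only when it falls at or below the fold's 10th-percentile
  influence cutoff in *every* fold, in a single pass. **Tree-count
  selection** takes, per fold, the argmax of the cumulative out-of-bag
  improvement smoothed by a 50-iteration moving average, then the maximum
  over folds ("encompassing" every fold's best; max was chosen over a
  consensus because the final model is refit on all rows, where extra
  iterations at a 0.005 learning rate are cheap and truncation is not).
  The final model is refit on 100% of rows with that tree count.
* Class imbalance (~9:1) is left unweighted, matching the practice this
  workflow reproduces; weights would change the probability scale that the
  0.5 suitability threshold interprets.

Evaluation metrics are shared definitions: rank-based AUC with midrank
ties; TSS = TPR + TNR − 1 at a threshold (default 0.5, matching the
suitability cutoff; the maximising threshold is also reported since the
choice is underdetermined); percent deviance explained
`(D_null − D_model)/D_null` with the null at the evaluation subset's own
label mean (not the training mean — held-out folds are scored as their own
universe). With a ~9:1 contrast ratio, probabilities concentrate below
0.5, so TSS at 0.5 is structurally much lower than max-TSS; AUC and
deviance explained are the threshold-free summaries.

# Mapping

`predict_surface()` assembles per-pixel predictor vectors (dynamic layers
nearest-not-after the prediction date), scores them with the fitted model,
and masks land and missing-predictor pixels. Suitability uses a strict
`> 0.5` threshold ("more likely than not": a pixel at exactly 0.5 is not
suitable). Areas are pixel counts times pixel area; the percent-of-area
denominator is the unmasked pixel count. Zone accounting assigns each
suitable pixel to the first listed zone containing its centre (even-odd
ray casting; bias at zone boundaries is at most one pixel width), with
percentages over zones plus "outside" summing to 100. Two-date comparison
reports both areas, `100·(b−a)/a` (undefined when the baseline is empty),
and a gained/lost/stable classification over the suitable union.

# Problem sizes and what the tests show

The acceptance run (`scripts/acceptance.R`) executes the full pipeline at
the package's study condition: a 128×128 scene (500 m pixels, 24 monthly
dates), 15 animals × 300 true steps, 9 pseudo-absence simulations per
track, and BRT with tree complexity 5, learning rate 0.005, bag fraction
0.75 and up to 2000 trees — about 700 presences and 6300 absences, a few
minutes end to end on one CPU. The test suite repeats a proportionally
reduced variant of the same design (64×64 scene, 12 dates, 10 animals ×
200 steps, 800 trees) over ten seeds to measure how often the two truth
predictors occupy the top two influence ranks; these sizes are the
package's chosen test design.

One finding of that repeated experiment deserves emphasis because it is a
property of the method, not of the code. The primary truth driver
(reef distance) tops the influence ranking in every seed, and the
cross-validated AUC is consistently high; but the *secondary* driver
(salinity) competes for second place with temperature, a predictor with
exactly zero truth effect, and loses in a substantial fraction of seeds.
The mechanism: temperature is nearly constant in space at any date, so a
split on temperature is effectively a split on *date*; because each
animal's track occupies a short date window, boosting can use such splits
to absorb track-level residual heterogeneity (some tracks are explained
better than others by the true drivers) and credits the resulting loss
reduction to temperature. Pseudo-absences share their presences'
timestamps, so this proxying cannot be removed by the contrast design;
dilution requires many animals overlapping in time. For users of such
pipelines on real data the implication is direct: high influence for a
spatially smooth dynamic predictor should be interpreted with caution
when tracking is temporally sparse, since it may reflect when the animals
were tracked rather than what they selected. The corresponding
truth-recovery test asserts rank stability for both drivers in at least
nine of ten seeds and is not met by this design; it is kept at that
strictness deliberately, as the honest measurement of the limit.

Passing on synthetic scenes demonstrates internal correctness —
parameter recovery, oracle equivalence, exact bookkeeping — under the
generator's assumptions: isotropic Gaussian telemetry error, step-valid
dynamic fields, a stationary movement kernel, truth effects on exactly two
predictors. It does not demonstrate performance on real tag data, whose
error distributions are heavy-tailed and state-dependent, whose
environmental layers carry shared spatial trends far stronger than the
synthetic fields, and whose animals switch behavioural states. In
particular, row-level cross-validation on autocorrelated telemetry is
optimistic; the fold-by-animal option exists for exactly that reason.

# Known limitations

* The CTCRW replaces move-persistence models; no behavioural index is
  produced.
* The speed/angle filter is this package's concrete definition, not a
  re-implementation of the published filters it approximates.
* Pseudo-absence steps and angles are resampled independently.
* The migration-onset rule is an automated proxy for visual judgement.
* No geodesy: synthetic scenes are planar; geographic input is handled by
  a CRS flag upstream of these functions but no reprojection engine is
  provided.
* Binned Bhattacharyya coefficients depend on the bin count (default 100).
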