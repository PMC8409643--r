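---
title: "Modelling trespass-cultivation risk with growrisk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trespass-cultivation risk with growrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Illegal ("trespass") cannabis cultivation sites on public forest land
are known only from presence records: law-enforcement agencies report
where sites were found, never where they searched and found nothing.
Mapping the landscape-scale risk of cultivation therefore calls for a
presence-background distribution model.  `growrisk` implements the full
analysis pipeline around an L1-regularized maximum-entropy (MaxEnt)
model: occurrence thinning, background sampling, focal predictor
smoothing, collinearity screening, stepwise variable reduction,
feature-type and regularization tuning by AICc, Boyce-index risk
classification, stream-survey validation statistics, and overlap of the
resulting risk classes with wildlife habitat layers and telemetry-based
home ranges.

## The model

Let $f(x) \in [0,1]^J$ be a vector of features built from the
environmental predictors at location $x$, and let $B$ be a sample of
background (availability) locations.  The model is the Gibbs
distribution over the background,

$$q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{\sum_{x' \in B}
e^{\lambda \cdot f(x')}},$$

whose weights maximize the penalized presence log-likelihood

$$\bar f_{\text{pres}} \cdot \lambda \;-\;
\log \frac{1}{|B|} \sum_{x \in B} e^{\lambda \cdot f(x)}
\;-\; \sum_j \beta_j |\lambda_j|.$$

At the optimum the background expectation of every feature matches its
presence mean to within the per-feature penalty ("the KKT box"):
$|E_q[f_j] - \bar f_{j,\text{pres}}| \le \beta_j$.  The maximum-entropy
reading is the same model from the other side: $q_\lambda$ is the least
informative distribution consistent with the presence data.

**Features.**  Three feature sets are supported, matching the sets the
classic tool exposes: `lqp` (linear, quadratic and all pairwise product
features of the scaled predictors), `hinge` (forward and reverse hinge
ramps at 50 knots per variable, knots at evenly spaced background
quantiles), and `auto` (all of the above).  Threshold and categorical
features are omitted; hinge features subsume thresholds in modern
practice.  All features are scaled to $[0,1]$ from training bounds, and
projection-time values are clamped into those bounds.

**Regularization.**  $\beta_j = r \cdot c(\text{class}, m) \cdot s_j /
\sqrt{m}$, where $m$ is the number of presences, $s_j$ the feature's
standard deviation over the presences (floored at $10^{-3}$ so the
problem stays bounded), $r$ the tunable multiplier, and
$c(\text{class}, m)$ the published per-class default schedule
(piecewise-linear in $m$ for linear/quadratic/product features; 0.5 for
hinges).

**Backgrounds.**  The presence samples are added to the fitting
background, as in the classic tool's default.  Without this, a feature
that is positive at a presence but zero at every background point has
no finite optimum; with it, every optimum is finite.  Raw output is
normalized over this fitting background; evaluation statistics (AUC)
are computed against the background points proper.

**Outputs.**  "Raw" output is $q_\lambda$ itself.  "Logistic" output is
the fixed-prevalence transform $e^H q / (1 + e^H q)$ with $H$ the
entropy of the fitted background distribution, giving values in
$(0,1)$ with 0.5 at an uninformative model.

**Optimizer.**  Greedy cyclic coordinate descent with guarded 1-D
Newton steps on an active set grown by KKT screening.  One *iteration*
is a single feature-weight update, mirroring the
one-feature-per-iteration semantics of the classic sequential
algorithm, and the default cap of 500 iterations per fit is the same as
that tool's default.  The cap doubles as a mild implicit regularizer on
desk-scale data; convergence, when reached, is declared at a maximum
projected gradient below `tol` ($10^{-5}$).  Percent contribution is
the per-update objective gain credited to the modified feature's source
variable (product features credit both parents equally), normalized to
100 — path-dependent, as in the classic tool, but deterministic given
the data.

## The pipeline and its tunables

| Tunable | Default | Meaning |
|---|---|---|
| `thin_distance` | 2000 m | minimum nearest-neighbour distance between retained occurrences |
| `n_background` | 10,000 | random availability points over the modelling extent |
| `focal_radius` | 450 m | radius of the focal mean applied to every predictor |
| `cv_folds` | 10 | cross-validation folds (each fold is the 10% test split) |
| `max_iterations` | 500 | optimizer weight updates per model fit |
| `reg_multipliers` | 0.5, 1, 1.5, 2, 3, 5 | multipliers tested in tuning |
| `feature_modes` | auto, lqp, hinge | feature sets tested in tuning |
| `correlation_threshold` | 0.7 | \|Pearson r\| above which variables are grouped |
| `isopleth` | 0.95 | home-range isopleth fraction |
| `min_locations` | 26 | minimum telemetry locations per home range |

Thinning removes the most crowded point repeatedly (ties broken by a
seeded draw) and then restores any point freed by later removals, so
the result is maximal.  Correlated variables (components of the
$|r| > 0.7$ graph over pooled presence + background rows) are reduced
to the member with the best univariate cross-validated AUC, ties going
to the lexicographically first name.  Stepwise jackknife reduction
removes, at each step, the variable whose omission yields the highest
mean test AUC, stopping when every removal would strictly lower it; the
retained set is the best state visited.  The surviving variables enter
an 18-combination feature-mode × multiplier grid scored by AICc, where
the likelihood uses raw output standardized to sum to one over the
projection grid, $K$ counts nonzero weights, and ties prefer the larger
multiplier, then the simpler mode.  The winning settings are refit on
all data and cross-validated; the pooled held-out logistic scores feed
the Boyce analysis.

Within one cross-validation run, features are defined once from the
full sample table — hinge knots come from the background, which every
fold shares — and each fold's fit is warm-started from the all-presence
fit.  This is purely an efficiency device: the optimization problem is
convex, so warm starting does not change any fold's optimum, and the
scaling bounds differ only microscopically from per-fold bounds.

## Risk classification

The continuous Boyce curve slides a window of width 0.1 across the
logistic range; each window's P/E ratio compares the fraction of
evaluation presences falling in the window with the fraction of the
landscape there.  The Boyce index is the Spearman correlation of P/E
with the window midpoint.  The low/moderate cut is placed where P/E
first reaches *and stays* at or above 1 (presences found at least as
often as availability predicts — the standard suitability boundary in
continuous Boyce methodology), and the moderate/high cut where it
stays at or above 2; the "stays" is enforced through the last
upcrossing so isolated dips in a noisy curve move the threshold up
rather than fooling it.  Both cuts can be overridden explicitly.  When
the curve jumps past both levels inside a single window the high class
begins at the following window.  Cells are labelled low $[0, t_1)$,
moderate $[t_1, t_2)$, high $[t_2, 1]$; areas are cell counts times
the 90 m cell area (planar CRS assumed throughout).

## What the synthetic landscape emulates

The generator produces spatially autocorrelated predictor fields
(Gaussian-kernel smoothing of white noise by FFT, correlation length
1200 m by default), percent slope derived from the synthetic elevation
by central finite differences, distance-to-feature layers from
generated roads, streams, private-land and disturbance masks (exact
Euclidean distance transform), plus a deliberately collinear
precipitation field (r ≈ 0.8 with elevation) so the correlation
grouping stage has real work.

The true selection surface is the inverse logit of band-shaped
responses: an elevation band centred at 1200 m (half-width 400 m, i.e.
800–1600 m), a slope band centred at 45% (30–60%), proximity to water,
and a mild canopy preference.  The band weights (20 and 18) and
intercept (−30) are strong, so suitability is effectively binary: high
only where both bands coincide (roughly a tenth of the landscape) and
near zero elsewhere.  This mirrors the real risk geography the analysis
is built for, where roughly three quarters of the modelled extent falls
in the low class, and it is what makes a 2000 m thinning survivable at
desk scale: on an 18 × 18 km landscape thinning keeps only ~15–25 of
500 presences, and any appreciable mid-suitability area would flood the
thinned sample with marginal points no model could rank.  Detection
bias is on by default (strength 8): a seed set of "previously found"
sites is smoothed into a search-effort density that multiplies the
sampling weight, emulating enforcement activity concentrated near known
sites.

Features of real data the generator does **not** emulate: mixed
positional error in localities, temporal drift in siting behaviour,
non-stationary selection across ecoregions, real hydrology and road
topology, and spatially structured detection failure.  Passing tests on
synthetic data therefore demonstrate the pipeline's correctness and its
ability to recover known structure — not field performance on any real
landscape.

Desk-scale problem sizes used throughout the package's own tests and
reproduction script: a 200 × 200 grid at 90 m, 500 presences, 2,000
background points (the paper-scale protocol uses 10,000, which remains
the package default), 10 folds, and the full 18-combination tuning
grid.

## Numerical choices and degenerate inputs

* Focal windows use all cells whose centers lie within the radius,
  truncated at edges, nodata excluded; output is nodata only for empty
  windows.  The "std" statistic is the population standard deviation.
* The distance transform is exact Euclidean (cell-center to
  cell-center).
* Constant predictors are excluded from feature expansion with a
  warning, and form singleton groups in collinearity screening.
* A constant suitability surface is rejected by the Boyce analysis; a
  P/E curve that never settles above 1 yields an all-low map with a
  warning rather than an error.
* Chi-square survey tests drop classes with zero surveyed length (they
  must also have zero observations) and report the continuous p-value.
* Home ranges need more than 25 locations; duplicated coordinates
  count with their multiplicity in isopleth coverage.  The adaptive
  parameter defaults to the maximum pairwise distance among the
  animal's locations — the standard heuristic, logged per animal and
  overridable.  Overlap percentages are measured on the rasterized
  hull union (cell-center rule) so they compose exactly with every
  other raster statistic.

## Open design decisions, resolved

* The 90/10 train/test split is realized *by* the 10-fold
  cross-validation: each fold serves once as the 10% test set.
* "500 iterations" is read as the optimizer's per-fit update cap — the
  cited tool's parameterization — not as 500 cross-validation
  repetitions.
* Univariate "default" models use auto features at multiplier 1.
* Tuning follows pruning, and the winning settings are refit on the
  full data ("prune → tune → refit").
* Boyce evaluation uses the pooled held-out fold predictions, not the
  training presences, so the classification thresholds reflect
  out-of-sample density.
* The latitude-adjusted elevation of the real analysis has no public
  formula; the package treats elevation-like layers as opaque inputs.
* Background points are neither thinned nor excluded at presence
  cells; filtering applies to occurrences only.

## Known limitations

* Percent contribution is optimizer-path-dependent; only its ranking
  should be interpreted, as with the classic tool.
* At desk-scale sample sizes (tens of presences after thinning) the
  default regularization schedule under-penalizes hinge features;
  the AICc tuning stage compensates by preferring sparser settings,
  but per-fold AUCs are noisy.
* Areas and distances assume a projected, metre-unit CRS; geographic
  coordinates are out of scope.
* The stream-survey chi-square reproduces the published *framework*;
  the published statistic itself is not reproducible because surveyed
  kilometres per class were not reported.
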