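---
title: "Methods: from SST and surveys to bleaching drivers and scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from SST and surveys to bleaching drivers and scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbleach)
```

`reefbleach` implements a complete analysis chain for archipelago-scale
coral bleaching: thermal-stress metrics from daily SST, a cover-weighted
taxonomic susceptibility score, spatial clustering with
information-based weights, a weighted drivers model with BIC-selected
interactions, and model-based perturbation/management inference. This
vignette explains the statistical machinery, the choices we made where
more than one defensible convention exists, and exactly what the
synthetic validation does and does not demonstrate.

## Thermal stress

Daily SST per island buffer is reduced to three quantities:

* **MMM** — the warmest calendar-month mean over the climatology years.
  By default the climatology uses every complete calendar year except
  the final (event) year of the record, so an ongoing heatwave does not
  inflate its own baseline. Leap days count in February.
* **HotSpots** — positive daily anomalies above MMM.
* **DHW** — HotSpots of at least 1 °C accumulated over the trailing 84
  days, divided by 7 (units: °C-weeks). The 1 °C accumulation floor
  follows the satellite heat-stress product convention (v3.1); the
  plain-language definition of HotSpot accumulation is ambiguous on this
  point, so the floor is exposed as `min_hotspot` (set 0 to accumulate
  every positive anomaly). The first 83 days carry partial windows and
  are flagged as spin-up.

The implementation is an O(n) running sum; tests verify it against a
brute-force window sum at 1e-9 and check translation invariance (adding
a constant to both SST and MMM changes nothing).

The per-cluster *acute* thermal stress used by the drivers model is the
event-window maximum DHW. Which window defines "acute" is a genuine
degree of freedom; we default to the survey-season window of the event
year and treat historical stress as the maximum over earlier event
years, both configurable. In synthetic mode the island-buffer mean is
supplied directly as a site index, mirroring a workflow where satellite
extraction happens upstream.

## Susceptibility score

`BS = Σ P_st S_t / P_s` weights each taxon's 1–5 susceptibility rank by
its share of live cover. Two consequences of taking the printed formula
literally are worth noting. First, live cover not attributed to any
scored taxon *dilutes* BS toward zero; we deliberately do not
renormalize by the scored cover, because the denominator is defined as
total live cover. Second, BS is invariant to rescaling all covers by a
common factor, so survey methods that report relative rather than
absolute cover agree after scaling. Species missing from the score table
fall back to their genus entry (reported per use); unresolvable taxa are
an error rather than a silent drop.

## Clusters, cells, weights

Surveys within 1 km of one another — irrespective of depth — belong to
one cluster. We read "within 1 km of one another" as a *diameter*
constraint and therefore use complete linkage: single linkage would
chain surveys into clusters whose ends are arbitrarily far apart.
Distances are haversine with mean Earth radius 6371.0088 km. Merges are
deterministic, with ties going to the pair containing the lowest survey
index; the tests verify the diameter contract by brute force over random
layouts and stability under permutation.

Within a cluster, surveys in each depth bin (shallow 0–6 m, mid
>6–18 m, deep >18–30 m; half-open bins with 0 in shallow) collapse to
one cell: mean % bleached, standard error (missing when n = 1), mean
BS, centroid. Zone × depth-bin combinations with fewer than three cells
are dropped entirely.

Weights are inverse standard errors, capped at their 95th percentile and
divided by it, so weights lie in (0, 1]; cells with missing SE receive
the 5th percentile of the raw weights *before* scaling. Three
conventions needed fixing where the procedure description leaves room:

* percentiles use linear interpolation between order statistics (R's
  default type 7);
* the 5th-percentile substitution happens on the raw (pre-scaling)
  scale;
* percentiles are pooled over the analysis set at hand rather than
  computed per region. For the drivers model the weights are computed on
  the post-filter analysis cells, so the cap reflects the set actually
  modelled.

An SE of exactly zero (identical replicates) is treated like a missing
SE rather than an infinite weight; if *no* cell has a positive SE the
weighting is refused — there is no information to weight by.

## Covariates

Ocean-colour pixels (PAR, kdPAR) are quality-masked where more than 5 %
of the pixel footprint is at depths of 30 m or shallower, computed from
a co-registered bathymetry grid at an integer-multiple finer resolution.
Extraction at a cell centroid returns the containing pixel when valid;
otherwise the search expands outward and returns the mean of all valid
pixels within the distance at which the first valid pixel was found
(default limit 8 km; 0.75 km is the conventional limit for wave
products). Because no raster stack is involved, grids are held in a
minimal regular lon/lat container with plain-text serialization.

Each driver is transformed (identity, `log1p`, or `sqrt`) and then
centred and scaled to mean 0, SD 1 over the analysis cells. The
transform choice is data-driven — non-negative variables with moment
skewness above 1 get `log1p` — with per-variable overrides, and the
fitted registry is recorded so predictions can be mapped back to natural
units. Standardization uses unweighted moments. Deep cells are excluded
from the drivers analysis, and any cell missing any driver is dropped
with a logged reason.

## The drivers model

The response is `sqrt(% bleached)` — a variance-stabilizing choice for
bounded percent data. The candidate set contains all driver main
effects plus two families of two-way interactions: acute DHW × each
other driver, and BS × each other driver, encoding the hypothesis that
drivers modify the bleaching–heat and bleaching–susceptibility
relationships rather than only shifting the mean.

Weighted least squares minimizes `Σ w_i (y_i − x_i β)²`. The BIC is
`n·log(wRSS/n) + k·log(n)` with `n` the number of cells (a weight is a
precision statement, not extra observations) and `k` the number of
coefficients. Backward selection removes, at each step, the single
eligible term whose removal most lowers BIC, stopping when none does.
Two rules make it reproducible and interpretable:

* **marginality** — a main effect is never removed while one of its
  interactions survives, which is why a weak main effect can legitimately
  stay in the selected model;
* **determinism** — ties are broken by alphabetical term order, and the
  search is pure backward (no re-addition).

The selected model is checked in the tests for local BIC-optimality
(no single eligible removal improves it) and agreement with an
independent stepwise implementation under the same penalty.

Spatial contrasts use a weighted one-way ANOVA with Tukey HSD on the
weighted group means, using per-group effective sample size `Σw` with
studentized-range critical values — an approximation appropriate to
weighted cell means, stated rather than hidden. Temporal contrasts use,
for the main islands, a weighted linear mixed model of year × zone with
island as a random intercept, fitted by maximum likelihood, with
likelihood-ratio tests for each term (interaction against the additive
model; each main effect against the additive model without it); for the
northwestern atolls, a weighted two-way ANOVA of year × island. Only
zone/island × depth-bin combinations surveyed in both years enter.

## Perturbation and scenarios

Predictions square the linear predictor and clip to [0, 100]; clipping
is counted because it signals extrapolation. With centred predictors,
every interaction vanishes at the all-means row, so the perturbation
baseline is exactly the squared intercept; each driver is then moved to
±1 SD alone. Partial-regression curves subtract the back-transformed
intercept contribution of the reduced model (the fit without the driver
and all its interactions); residual points are carried with their
weights.

The management scenario keeps each cell's *observed* driver values —
rather than setting everything to means — and overrides only acute DHW,
fixed at the 95th percentile of the analysis cells (computed over cells,
not surveys; the quantile is configurable). Each manageable driver is
reduced by 1 SD in turn on the standardized scale, and the best action
per cell is the largest predicted reduction, ties broken alphabetically.
This design follows the view that a manager acts on a site as it is, not
on an average site.

## The synthetic generator and what validation shows

`simulate_bundle()` draws, per cluster, standardized drivers from a
correlated Gaussian field (anthropogenic indices share a configurable
pairwise correlation, default 0.4), maps them to natural scales, builds
each cell's expected `sqrt(%)` response as an exact linear combination
under a known coefficient vector, adds cell-level noise (SD 0.5 on the
sqrt scale), and replicates surveys with within-cluster noise (SD 5 %),
clamping percentages to [0, 100] after noise. Survey taxon compositions
are mixtures of two adjacent-score taxa chosen so each survey's BS
equals the cell's susceptibility driver exactly. The cluster layout is a
deterministic hexagonal-offset grid with jitter, guaranteeing surveys
within a cluster are < 1 km apart and clusters > 2 km apart.

Two design choices deserve emphasis:

* **Linear natural-scale maps with exact in-sample standardization.**
  The generator standardizes its driver draws within the sample and maps
  them to natural units linearly. The pipeline's re-standardization then
  reproduces the generating design *exactly*, which is what makes "the
  true coefficient" a well-defined target at finite n. With nonlinear
  maps (exercised separately in the transform tests) the estimand would
  differ from the generating coefficients by Jacobian terms.
* **Clamping-induced bias.** Clamping to [0, 100] after noise, together
  with the concavity of the square root and inverse-SE weighting,
  attenuates coefficients slightly — most visibly for the largest
  effect. At the default settings (baseline ≈ 20 % bleached, replicate
  SD 5 %) the mean attenuation is below 0.05 on the sqrt scale for every
  term, which the recovery tests assert over 20 seeds. At more extreme
  means (cells near 0 % or 100 %) the bias grows; this mirrors what a
  bounded response does to real analyses and is a caveat, not a bug.

Passing recovery tests therefore show that the pipeline's *mechanics* —
scoring, clustering, aggregation, weighting, standardization, fitting,
selection — introduce no material distortion under the generator's
assumptions: linear truth, Gaussian drivers, symmetric noise, correct
spatial separation. They do not show robustness to model
misspecification, spatially correlated residuals beyond the cluster
scale, measurement error in drivers, or taxonomic mis-scoring; real
survey programs face all four.

Problem sizes in the test-suite experiments were chosen to keep the
whole suite fast while leaving clear statistical margin: recovery runs
use 20 seeds at 200–300 cells; the selection experiments use 50 seeds at
n = 300–500 with 6–8 candidate terms.

## Degenerate inputs and numerical conventions

* SST gaps of up to 3 days are linearly interpolated; longer gaps are
  refused. A missing calendar month fails MMM with the month named.
* A survey with zero live coral cover has no defined BS and is excluded
  with its reason recorded; an unresolvable taxon is an error.
* Rank-deficient designs are refused naming the aliased terms.
* All tolerances used in tests are absolute: 1e-12 for the BS oracle,
  1e-10 for WLS against closed-form normal equations, 1e-9 for DHW
  against brute force.
* Every stochastic component is behind a single integer seed; pipeline
  reruns with unchanged inputs are byte-identical.

## Known limitations

* Zone assignment is taken as an input (or generated synthetically);
  the package does not reconstruct zone polygons from monitoring data.
* The Tukey procedure on weighted means is an approximation; exact
  small-sample behaviour under heteroskedastic weights is not claimed.
* Scenario outputs are associational: "best action" ranks model
  predictions, not causal effects.
* Uncertainty bands on scenario rankings are not provided; a bootstrap
  over cells would be the natural extension.
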