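---
title: "Methods: eye-level greenness exposure and multilevel walking models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-level greenness exposure and multilevel walking models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most population studies of urban greenness and physical activity measure
greenness from overhead (park area, tree counts, satellite indices such as
NDVI). What a pedestrian actually sees at street level can differ
substantially, especially under dense canopy or where vegetation is
vertical. `greenwalk` implements the alternative: **eye-level greenness**
measured from street-level imagery via the *green view index* (GVI), linked
to walking behaviour with street-block multilevel models.

The package is built to be *fully synthetic-runnable*: every input a real
study would obtain from GIS layers, street-imagery services and a travel
survey can be generated from seeds, with known ground truth, so the whole
analysis chain can be validated by parameter recovery — simulate outcomes
from known coefficients, refit, and check the coefficients come back.

## The exposure model

At a street sampling point, four tiles with a 90-degree field of view are
taken at compass headings 0/90/180/270, covering the full panorama. The GVI
pools pixels over the four tiles:

$$\mathrm{GVI} = \frac{\sum_{i=1}^{4}\text{greenery pixels}_i}
                      {\sum_{i=1}^{4}\text{total pixels}_i} \in [0, 1].$$

This is a pooled integer ratio, *not* a mean of per-tile ratios — the two
differ whenever tile sizes differ, and `green_view_index()` returns the
pooled value. Sampling points are placed along street centerlines at 50 m
arc-length intervals (per edge, from the edge's start node; node-coincident
duplicates removed by rounding coordinates to 0.01 m). A dwelling's
neighbourhood exposure is the **unweighted mean** GVI over the points inside
a Euclidean disk of radius 400 m or 800 m around the dwelling — two radii
(roughly 5 and 10 walking minutes) so that conclusions can be checked for
sensitivity to the aggregation unit. Points are kept on the *closed* disk;
a dwelling whose buffer contains no street point has no defensible exposure
value and is dropped with a logged count.

Two radii require the greenness surface to be spatially structured: the
synthetic vegetation field is a Gaussian random field with a 300 m
correlation length (FFT-smoothed white noise, logistic-squashed to [0, 1]),
so 400 m and 800 m buffer means differ but correlate, as observed in real
cities.

## The synthetic city

`generate_city()` builds, from a seed, a planar city in meters (no geodesy;
all distances of interest are sub-kilometre, so circular buffers are
Euclidean disks):

* **street network** — a jittered grid (default 160 m spacing) with a small
  fraction of edges dropped and diagonal connectors added; connectivity is
  repaired with a union-find pass so the network is one component and 50 m
  sampling is defined everywhere. A jittered grid gives realistic variation
  in intersection density, unlike a uniform lattice or a random geometric
  graph.
* **street blocks** — Voronoi regions of random seed points (default 200),
  the census-like clustering unit of the multilevel models. Seeds are drawn
  inside the dwelling core (see below) so housing estates occupy essentially
  every block.
* **land-use parcels** — square cells (default 250 m) labelled
  commercial/office/residential with lognormal population weights.
  Population loads all three types (residential most heavily) so density is
  not a deterministic function of the use mix; an early design that put
  population only in residential parcels made population density and
  land-use entropy collinear (|r| ≈ 0.7), which no covariate screen would
  accept.
* **amenities** — shops (biased toward commercial parcels), recreation
  facilities, bus stops and rail stations as point sets.
* **dwellings** — `place_dwellings()` assigns each dwelling to a block
  (gamma-weighted, so block sizes vary), scatters it 60 m around the block's
  estate anchor (public-housing estates are compact), and keeps all
  dwellings at least 800 m from the extent boundary so no buffer is ever
  truncated. The default extent is 12 km: 800 m disks tile the dwelling
  core into ~40 effectively independent neighbourhoods, enough that chance
  correlations between unrelated buffer covariates stay small across seeds
  (maximum VIF well below 2). At a 4 km extent we measured chance
  cross-covariate correlations above 0.6 — an aggregation artefact, not a
  generator property — and at 8 km the screen still failed for occasional
  seeds.

## Streetscape rendering and segmentation

`render_tileset()` draws each tile (default 256×256) with sky, building
facades, road, and vegetation as thresholded smooth-noise blobs in a green
hue range with strong per-pixel value noise (foliage texture). The expected
vegetation fraction of a tile tracks the vegetation field at the point, and
the truth mask is exact. With configurable probability a tile also contains
**man-made green confounders** — smooth, rectilinear patches (trucks, painted
walls) whose pixels are *not* vegetation — the classic failure mode of
colour-only greenness extraction.

`segment_vegetation()` is a deterministic, rule-based stand-in for a trained
semantic-segmentation network, behind the same mask contract (a real model
could be wired in instead; `fetch_gsv_tileset()` documents where live
imagery retrieval would plug in). It combines

1. a hue/saturation/value gate for green pixels (hue 0.195–0.47 ≈ 70–170°,
   saturation ≥ 0.15, value ≥ 0.08), and
2. a shape/texture filter on connected components: components that are both
   rectilinear (bounding-box fill > 0.93) and painted-smooth (value-channel
   SD < 0.05), or smoother than any foliage (SD < 0.015), or tiny
   (< max(6, 10⁻⁴·HW) pixels), are removed.

Thresholds were chosen on exploratory renders before the validation corpus
was fixed. Validation mirrors expert relabelling: per-image predicted vs
ground-truth green fractions over a 50-image corpus, summarised by Pearson
r (`validate_segmenter()`); the correlation is computed on image-level
fractions, not pixels. Segmentation is idempotent, and on corpora with
confounders the shape-aware segmenter has strictly smaller mean absolute
fraction error than the colour-only gate — the filter's reason to exist.

## Covariates

`buffer_covariates()` computes, per dwelling and radius: population density
(parcel population apportioned by the parcel-area share inside the disk,
per km²), land-use mix as normalized entropy over the three use shares
(−Σp·ln p / ln 3 with 0·ln 0 ≡ 0, so 0 = single use, 1 = even mix),
intersection density (network nodes of degree ≥ 3 per km²), counts of
shops/recreation facilities/bus stops, and Euclidean distance to the
nearest rail station (not capped at the radius). Parcel–disk area integrals
are evaluated on a 25 m raster (dwellings snapped to cell centres for that
step); at that resolution the approximation error is far below the
between-dwelling variation the models consume.

Continuous predictors are z-scored (sample SD, n−1) **on the analysis
sample actually fitted** — the full cohort for the walking-decision model,
the walker subsample for the walking-time model — so coefficients read as
per-SD effects in each analysis. Age (5–17 reference, 18–44, 45–64, ≥65)
and household income (low reference, then medium-low/medium-high/high) are
dummy-coded; these band edges follow the study's descriptive table. Gender
enters effect-coded (−½ male, +½ female), so the main greenness slope is the
gender-averaged slope and stratum slopes are main ± ½·interaction; this is
the coding under which published stratified odds ratios straddle the main
one.

Collinearity screening (`vif()`, VIF = 1/(1−R²)) is applied to the
**continuous** predictors. Mutually exclusive dummy sets mechanically
correlate through their margins (an age dummy at realistic shares reaches
VIF ≈ 2.2 with no substantive collinearity at all), so including them would
make the screen meaningless; the usual practice for this screen is
continuous variables only, and that is what the package reports.

## The multilevel models

Both outcome models have a Gaussian random intercept per street block,
implemented from scratch in `fit_logistic_ri()` / `fit_linear_ri()`.

**Logistic (walking decision).** The marginal likelihood
$\prod_j \int \prod_i \mathrm{Bern}(y_{ij}\,|\,\mathrm{logit}^{-1}(x_{ij}'\beta+b))\,
\varphi(b;0,\sigma_u^2)\,db$
is evaluated by *adaptive* Gauss–Hermite quadrature: per group the integrand
is recentred at its posterior mode (a safeguarded Newton step on the
log-concave conditional) and rescaled by the curvature there, then K = 15
nodes are applied (Golub–Welsch nodes/weights computed in-package). With
200+ groups of ~125 observations, non-adaptive quadrature at modest K is
badly placed; adaptivity keeps K = 15 within 10⁻⁶ of a fine-grid
integration oracle, and K = 15 vs K = 51 agree to the same tolerance.
The score is computed by the Fisher identity — the gradient of the marginal
log-likelihood equals the posterior expectation of the complete-data score —
with the same quadrature rule, giving a quasi-Newton (BFGS) optimisation on
(β, log σᵤ) that converges in seconds at n ≈ 25,000. Standard errors come
from the observed information (central differences of the analytic score);
odds ratios and 95% intervals are Wald on the log scale, which matches the
symmetric exp-scale intervals convention. Up to three restarts from
perturbed starts are attempted on non-convergence; degenerate responses
(all 0/1, complete separation of the intercept) are flagged rather than
chased. With σᵤ fixed at 0 the fit reduces exactly to plain logistic
regression.

**Linear (walking time).** Profiled maximum likelihood over the variance
ratio λ = σ_b²/σ_e²: given λ, β is closed-form GLS (per-group Woodbury
inverse, so only group sums are needed) and σ_e² is closed-form given β;
the profile deviance is minimised in log λ with an explicit λ = 0 (OLS)
boundary check. ML is the default so AIC/BIC are comparable across
fixed-effect specifications; REML is available by flag. On balanced designs
the ML estimates match the closed-form one-way ANOVA components, and on
general designs the fit matches `lme4::lmer(..., REML = FALSE)` to
optimizer precision (lme4 serves as an independent cross-check in the test
suite, never as the implementation).

**ICC.** Gaussian: σ_b²/(σ_b²+σ_e²). Logistic: the latent-threshold
convention σᵤ²/(σᵤ²+π²/3), the standard choice when a single null-model ICC
is reported for a binary outcome.

**Post-hoc stratification.** `simple_slopes()` forms stratum slopes
main + w·interaction with the moderator's coding weight and delta-method
standard errors from the coefficient covariance; because the stratum slope
is linear in the coefficients, this equals re-fitting with the stratum as
reference, which the tests verify.

## Outcome simulation and parameter recovery

`gm_walk()` / `gm_walktime()` hold the generating fixed effects — by default
the published per-buffer coefficient sets (log odds ratios for the decision
model; standardized betas for the time model) — plus variance components
set from the published null-model ICCs: σᵤ² = ICC/(1−ICC)·π²/3 = 0.282
(ICC 7.9%) for the decision model, and σ_b² = 0.16, σ_e² = 0.84 (ICC 16%,
unit conditional variance) for the time model. The decision-model intercept
(baseline log-odds for a child in the low-income band, gender-averaged) is
not published; we use −0.3, which yields a plausible ~30–40% walking
prevalence — recovery of slopes is insensitive to this choice. The
walking-time model is simulated and fitted on the standardized outcome
scale (published coefficients are standardized betas); conversion to
minutes is a fixed affine presentation transform (60 + 25·y) floored at
1 minute with the floor count logged.

Cohort demographics are drawn independently from the study's marginal
composition (`cohort_margins()`): full-cohort margins for the decision
analysis (n = 24,773), walker margins for the time analysis (n = 1,994,
placed in a 150-block subsample). The recovery protocol
(`recover_walk()`, `recover_walktime()`, `recover_null_icc()`) fixes the
geography (city, dwellings, exposures, covariates) once, then per replicate
redraws demographics, block intercepts and outcomes, refits, and averages
the target quantity over 20 seeded replicates. At these sample sizes the
Monte-Carlo standard error of the mean recovered greenness odds ratio is
about 0.01, an order of magnitude inside the reported interval widths.

## Problem sizes and computational choices

Defaults used by the recovery runs and the test suite: 12 km city, 200
blocks, 24,773 dwellings, 400/800 m radii, 50 m spacing (~37,000 deduplicated
network points), 20 replicates per target; full-cohort exposure uses the
ground-truth vegetation field at sampling points (the rendered+segmented
path is the same pipeline surface, validated on the 50-image corpus and
shown to agree with the truth-mask path at small scale — rendering
~10⁵ tilesets per cohort would add nothing statistically). Unit tests use a
1.6 km city and 48–64 px tiles. A full logistic fit at survey scale takes
roughly 10 s single-threaded; one complete recovery target (20 replicates)
about 3 minutes.

## What the synthetic conditions do and do not show

Passing recovery shows the *pipeline* is correct and unbiased under the
stated generating process: exposures measured as specified, models fitted
by correct maximum likelihood, coding conventions consistent end to end. It
does not validate the substantive claims on real data: real exposure error
is not the renderer's, real demographics are not independent of geography
(no residential self-selection exists in the generator by construction),
walking is self-reported with recall bias, and circular buffers ignore real
pedestrian infrastructure (footbridges, elevated walkways). Network
(shortest-path) buffers, safety covariates, trip-level outcomes and crossed
or random-slope designs are out of scope.

## Interface note

The package's interface is its functions (`run_analysis1()`,
`run_analysis2()`, the module functions above) plus plain-text exporters
(GeoJSON for geometry, CSV for tables, JSON for configurations, fits and
validation reports, PNG for tiles); an R analysis package of this kind is
driven from R scripts and this vignette rather than a shell CLI.
`scripts/acceptance.R` is the reproduction entry point.
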