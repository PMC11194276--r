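---
title: "Methods: seasonal RSFs under intraguild predation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal RSFs under intraguild predation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open: what is estimated, under which
assumptions, with which defaults, and what the synthetic-data tests do and
do not demonstrate about field data.

## The estimation problem

Both carnivore stages estimate an exponential resource selection function
(RSF), `w(x) = exp(β'x)`, at the second order of selection: locations are
treated as exchangeable draws within a season whose intensity over space is
proportional to `w(x)` inside a population range. Estimation is by
used–available logistic regression: telemetry fixes are labelled 1, and
`ratio = 10` random points per fix, drawn uniformly from the population
range, are labelled 0. The logistic slope vector converges to the `β` of
the exponential intensity as the available sample grows; the intercept only
encodes the used:available ratio and is therefore dropped when `w(x)` is
mapped as relative probability of use (RPU). We fit the plain (unweighted)
logistic likelihood; the infinitely-weighted refinement of the available
points is deliberately not the default because at 10:1 the slopes are
already stable and the plain fit keeps every diagnostic (AUC, AICc,
residuals) in its standard form.

Assumptions worth stating plainly: no movement autocorrelation (fixes are
treated as independent), availability identical for all animals of a
species (one pooled population range), perfect detection, and covariates
measured without error at the cell of each location.

## Population range and availability

The availability domain is the 99% isopleth of a Gaussian kernel density
estimate of all pooled locations, computed exactly on the analysis grid.
Bandwidth is Scott's reference rule per axis, `sd · n^(-1/6)` (metres);
it is recorded in the returned object so a run can be reproduced. The mask
is the smallest set of highest-density cells whose summed mass reaches the
isopleth, which makes the nesting property (a 50% range is inside the 99%
range) exact by construction. Available points are uniform over mask cells
and uniform within a cell. For the predator stage the same construction
doubles as the availability domain for prediction; a user-supplied polygon
can replace it when the availability frame is defined administratively
rather than behaviourally.

## Covariates and transforms

* distance-to-feature covariates are `ln(d + 1)` of the Euclidean
  cell-center distance in metres — the `+1` keeps cells that lie on a road
  or water source (d = 0) finite;
* elevation is centered and scaled to SD 1 (sample SD, denominator n − 1);
  the `(mean, sd)` pair is stored and replayed verbatim on prediction
  layers;
* vegetation and soil are reference-coded categoricals; barren is the
  vegetation reference and blocky loam the soil reference, so soil
  coefficients read as selection relative to the hardest-to-dig substrate;
* distance to water is log-transformed by default (`log_water_distance`
  flag); the raw-scale alternative is retained because a raw-metre
  coefficient is sometimes wanted for comparison with published per-metre
  effects;
* the predator RPU surface fed to the subordinate stage is rescaled by its
  maximum into (0, 1]. An RSF is defined only up to a multiplicative
  constant, so this is inferentially a no-op; numerically it keeps the
  second-stage design well conditioned (the raw surface spans several
  orders of magnitude) and makes RPU coefficients comparable across
  seasons.

Season is derived from the fix timestamp: April–September is summer,
October–March winter, and a winter spanning the year boundary is labelled
by the year of its October. Time-varying covariates (the prey rasters) are
joined to each point — used or available — by that point's season-year.

## The prey index

Small-mammal summaries are mean individuals per trapping grid per
(vegetation, season-year); leporid summaries standardize sighting counts as
`'# of sightings' / '% available'` with availability on the 0–100 percent
scale (so 40 sightings over 50% availability scores 0.8). Because
transects differ in composition, the per-class index is computed per
transect and averaged over the transects where the class is available.

Quartile ranking assigns 1 (low) to values at or below Q1, then
right-closed intervals (Q1, Q2], (Q2, Q3], and 4 (very high) above Q3.
Quartiles are linear-interpolation (type 7) quantiles of the pooled values
for the taxon across the whole study period; per-season pooling is
available (`pooled = FALSE`) because the phrase "for each season of all
study years" admits both readings, but pooling across the period is the
default as it keeps one scale per taxon. All-equal inputs rank 1
everywhere — a deliberate consequence of the "at or below Q1" boundary
rule.

The combined prey raster is `2/3 · small mammal + 1/3 · leporid` on the
rank scale, weights reflecting the taxa's contribution to the subordinate
predator's diet. Where exactly one taxon is ranked (the leporid layer has
the larger NA footprint), the available rank is used alone rather than
propagating NA; `strict = TRUE` switches to propagation. Cells with
neither rank stay NA and any design row touching one is dropped and
counted.

## Fitting, selection and evaluation

The likelihood is maximized by IRLS (`stats::glm`), then polished with
full Newton steps until the score norm `‖X'(y − p)‖` is below 1e-8 —
IRLS alone stops on relative deviance change and can leave the score near
1e-5 on large designs. A fit reports `converged` only when the final score
norm is below 1e-6. Constant columns, rank deficiency and perfect
separation (runaway coefficients with saturated fitted probabilities) are
surfaced as errors naming the covariate. Wald CIs use the inverse observed
information; the `significant` flag marks intervals excluding zero.

Candidate models are compared by AICc, `−2logL + 2k + 2k(k+1)/(n−k−1)`,
with `n` the number of likelihood rows (used + available). ΔAICc ≤ 2
flags a model parsimonious; a best model is decisive when its margin over
the runner-up exceeds 2. Cross-validation stratifies the folds by case so
every fold keeps the 10:1 ratio; the held-out rows are scored by linear
predictor and summarized by the rank-based (Mann–Whitney) AUC with ties
counted one half — chosen over trapezoid integration because it is exactly
reproducible and directly checkable against an all-pairs oracle. Pearson
correlation above 0.7 between continuous covariates drops the
later-priority member of the pair before fitting. Residual spatial
structure is checked with an empirical semivariogram of Pearson residuals
(equal-width lag bins to half the extent diagonal by default; computed on
a subsample of at most 1,200 rows since the all-pairs cost is quadratic).

## What the synthetic generator emulates — and what it does not

The generator reproduces the study conditions the pipeline ingests:
vegetation drawn to the study-area mixture (31.3% desert scrub, 21.1%
grassland, 17.4% sagebrush, 14.8% forest, 10.9% barren, 4.2% shrubland,
0.3% developed), four soil substrates, elevation spanning 1298–3317 m,
16 trapping grids with two sessions per year, spotlight transects with a
400 m availability strip, 4-hourly GPS fixes for the predator and ≥ 30
VHF fixes per animal-season for the subordinate. Categorical and
continuous fields are thresholded smoothed Gaussian random fields, not
i.i.d. cells, so semivariogram diagnostics have spatial structure to
exercise; class thresholds sit at the field's empirical quantiles, which
pins realized proportions to the mixture up to cell rounding.

Telemetry is an independent inhomogeneous point process with intensity
`exp(β'x)` — exactly the model the fitting stage assumes. Passing
recovery tests therefore shows the estimation machinery is correct and
unbiased *under its own assumptions*; it does not show robustness to
movement autocorrelation, telemetry error, imperfect detection or
availability misspecification, none of which the generator produces.

Truth coefficients default to the adaptive-compromise sign structure:
predator-RPU and prey selection positive in both seasons but clearly
stronger in winter, silt and fine sand preferred over blocky loam over
gravel. The RPU coefficients (0.4 summer, 1.5 winter) are expressed on
the pipeline's own max-normalized (0, 1] RPU scale and are chosen to be
comfortably estimable at the simulated sample sizes; published
coefficients from field studies are on their own unstated RPU scales and
are not transferable, so no numerical equivalence is intended.

One structural caveat the simulation shares with the real design: within a
single season-year the prey raster is a deterministic reclassification of
vegetation, so in the predator model (which contains both) the prey
coefficient is identified only by between-year variation in the rankings.
Its estimate is accordingly attenuated and wide — visible in the worked
example, where elevation recovers near truth while prey shrinks toward
zero in one season.

## Problem sizes and numerical defaults

Test-suite and acceptance runs use grids of 50–120 cells per side at
100 m resolution, 1,000–2,000 used points with ratio 10, 100–200
replicates for recovery and coverage, and 5-fold CV on designs of about
20,000 rows — sizes at which every stochastic check has comfortable
Monte-Carlo margins while a full run of suite plus acceptance script
completes in a few minutes. Other defaults: KDE isopleth 0.99; minimum 30
locations per animal-season; GLM deviance tolerance 1e-10 with up to 25
Newton polishing steps; semivariogram 12 lag bins. Seeds enter every
stochastic function explicitly; all simulators are pure functions of
(configuration, seed), which is what makes the end-to-end manifest-hash
reproducibility test possible.

## Known limitations

* No mixed effects: data are pooled across animals, as second-order
  designs commonly do; per-animal designs are available only as a
  sensitivity path.
* The KDE range depends on the grid resolution at which it is evaluated;
  isopleth coverage is exact on cells, not on continuous space.
* The quartile ranks discard within-class abundance variation by
  construction; two classes just across a quartile boundary differ by a
  full rank.
* Distance surfaces are exact Euclidean cell-center distances; there is no
  notion of barriers or travel cost.
* AICc uses the used+available row count as `n`; the correction term is
  tiny at these sizes, but `n` is not a biological sample size and AICc
  differences should be read within, not across, designs.
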