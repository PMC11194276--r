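# igprsf

Seasonal resource selection functions (RSFs) for a desert carnivore guild
under intraguild predation — a dominant predator (coyote, *Canis latrans*)
and a subordinate one (kit fox, *Vulpes macrotis*) sharing small-mammal and
leporid prey in Great Basin cold desert. The package is for spatial and
movement ecologists who want the full two-stage workflow — prey indexing,
predator RSF, subordinate RSF with predation-risk covariates — as tested,
reusable functions, with a synthetic-data module that makes every stage
verifiable by parameter recovery.

## The model

Habitat selection is modelled at the second order (placement of home ranges
within the population range) with the exponential RSF

    w(x) = exp(β₁x₁ + β₂x₂ + ⋯ + βₙxₙ)

estimated by used–available logistic regression: observed telemetry fixes
(case = 1) are contrasted with 10 random locations each (case = 0) drawn
uniformly from the population range, the 99% isopleth of a Gaussian kernel
density estimate of all pooled locations. The fitted slopes are the log
selection strengths; the intercept absorbs the sampling ratio and is
excluded when `w(x)` is predicted across the landscape as relative
probability of use (RPU).

The workflow has two stages:

1. **Predator stage** — seasonal (summer Apr–Sep, winter Oct–Mar) coyote
   RSFs on prey abundance, centered/scaled elevation, vegetation class
   (barren reference), log distance to roads and distance to water;
   evaluated by fivefold cross-validated AUC (0.5–0.7 low, 0.7–0.9 useful,
   >0.9 high) and predicted as seasonal RPU rasters.
2. **Subordinate stage** — seasonal kit fox RSFs with coyote RPU, prey
   abundance, soil substrate (silt, fine sand, gravel vs. blocky-loam
   reference) and log road distance; three candidate models (base,
   base + soil, full) ranked by AICc with ΔAICc > 2 decisive.

Prey abundance is an ordinal raster built from surveys: mean individuals
captured per trapping grid (small mammals) and spotlight sightings
standardized as `'# of sightings' / '% available'` within a 400 m strip
(leporids), each quartile-ranked 1–4 (low … very high) against the pooled
study-period values, reclassified over the vegetation raster, and combined
2/3 small mammal : 1/3 leporid.

## Worked example

The analysis is organised as numbered drivers under `analysis/` that
simulate a study system with known selection coefficients and push it
through both stages:

```sh
Rscript analysis/01_simulate_study.R   # landscape, surveys, telemetry
Rscript analysis/02_prey_index.R       # seasonal prey rasters
Rscript analysis/03_fit_coyote.R       # predator RSF + RPU rasters
Rscript analysis/04_fit_kitfox.R       # subordinate RSFs + AICc tables
Rscript analysis/05_report.R           # hashed artifact manifest
```

Output of a run (seed fixed in the scripts):

```
summer: n_used 800, AUC 0.739 (useful); prey beta -0.013, elevation beta -0.546
winter: n_used 800, AUC 0.748 (useful); prey beta 0.056, elevation beta -0.612
truth: prey 0.25 elevation -0.6
...
summer: 6 animals, n_used 2160; best model full (delta to runner-up 3.60);
    coyote RPU beta 0.457 [-0.319, 1.234], prey beta 0.018 [-0.040, 0.077]; AUC 0.575
winter: 6 animals, n_used 2160; best model full (delta to runner-up 86.98);
    coyote RPU beta 1.598 [0.931, 2.264], prey beta 0.275 [0.226, 0.324]; AUC 0.633
```

Read: the coyote elevation coefficient is recovered near its simulated
value (−0.6); the coyote prey coefficient is attenuated because prey is a
deterministic reclassification of the vegetation covariate within any one
season-year and is identified only by between-year variation (the vignette
discusses this). In the fox stage the winter fit shows the simulated
adaptive-compromise pattern — selection for coyote RPU (1.60, CI excluding
0) and for prey (0.28) both clearly stronger than in summer — and the full
model wins decisively in winter (ΔAICc ≈ 87) while the summer margin is
small.

Each fitted coefficient table (`results/*/**_coefficients.csv`) has
columns `term, estimate, se, lower, upper, p_value, significant`; model
comparisons carry `aicc, delta, parsimonious`.

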