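---
title: "Mapping oak woodland with a constrained ensemble distribution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping oak woodland with a constrained ensemble distribution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakmap)
```

## The problem

National woodland maps typically resolve habitat to "broadleaved",
"conifer" or "mixed"; they do not say which broadleaved polygons are
oak-dominated. Where a country has (i) a detailed stand map for part of the
forest estate, (ii) regional totals of stocked oak area, and (iii) a
plot-sample elevation distribution of oak stands, those three sources can
be combined with a species distribution model (SDM) to allocate
"predicted oak" to the broadleaved polygons. oakmap implements that
pipeline end to end, together with a synthetic landscape generator so the
whole method can be exercised and tested without access to confidential
forest inventories.

The pipeline has five stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **simulate** – a seeded synthetic landscape (or, in a real application,
   the corresponding external data);
2. **prepare** – balanced presence/pseudo-absence pixel tables and
   collinearity screening;
3. **fit** – the four-learner ensemble with repeated split-sample
   cross-validation, scored and weighted by the true skill statistic (TSS);
4. **filter** – masking to broadleaved polygons, probability ranking, an
   area-target filter and an elevation-histogram filter;
5. **validate** – coincidence against independent sites with exact
   binomial statistics.

## Presence, absence and prevalence

Stands with an oak canopy component of at least 60% of the stand area are
presence stands; broadleaved stands whose oak component is absent or at
most 10% supply pseudo-absence candidates. Stands in between belong to
neither class and contribute no training pixels. Pixel membership is by
pixel centre, and any pixel carrying a NoData covariate is dropped and
counted.

Because absence candidates vastly outnumber presences, training sets are
balanced at prevalence 0.5: 15 independent absence replicates are drawn,
each exactly matching the presence count, sampled without replacement
within a replicate (replicates may overlap — the pool is sampled
independently each time). A `presence_fraction` option (default 0.5)
subsamples the presence pixels first, so that individual model runs do not
reuse every presence pixel. All draws are seeded.

## Collinearity screening

Before fitting, covariates are screened per region: while any pairwise
|r| exceeds 0.7 or any variance inflation factor (VIF, `1/(1 - R^2)` from
regressing one covariate on the rest) exceeds 10, the offending variable
least related to the presence/absence response (smallest squared
correlation) is removed. The thresholds are configurable and recorded in
the report; 0.7 and 10 are the field's conventional defaults. Constant
columns are removed first with a warning. In the synthetic landscape this
screening reliably removes most of the elevation-duplicated climate
columns (DEM, AT and CMD are near-collinear by construction), mirroring
how a real screening retains one representative of the elevation channel
per region.

## The ensemble

Four learner families are fitted: logistic regression (GLM),
gradient-boosted trees (GBM, via xgboost: 100 rounds, depth 3, learning
rate 0.1), random forest (RF, via ranger: 500 trees) and a single
hidden-layer neural network (ANN, via nnet: 8 units, weight decay 0.01).
Hyperparameters are fixed, documented defaults — the method is not a
hyperparameter search, and the ensemble is designed to tolerate individual
learners being mediocre.

For each of the 15 absence replicates, a stratified 50/50 split (repeated
30 times) trains each learner on one half and evaluates it on the other,
preserving prevalence 0.5 in both halves. Skill is the true skill
statistic,

> TSS = sensitivity + specificity − 1,

evaluated at the threshold in {0, 0.01, …, 1} that maximises it (ties
resolved towards the smaller threshold). The threshold rule is our
convention: it is the standard practice for converting SDM scores to
classes when the original platform's rule is not specified, and it is
recorded in the run ledger alongside every TSS value.

Runs that raise a fitting error or return non-finite predictions are kept
in the ledger with `converged = FALSE` and excluded from averaging; an
algorithm whose converged fraction falls below 0.5 in a region is dropped
from that region's ensemble entirely (mirroring how unstable learners get
removed region-wise in practice). The ensemble surface is the weighted
mean of converged run predictions with weights `max(TSS, 0)`:

> P(pixel) = Σ w_i p_i(pixel) / Σ w_i.

Negative-TSS runs receive weight zero, keeping the combination convex, so
the ensemble is bounded by the contributing runs pixel-wise and invariant
to rescaling all weights. Weighting is per run in one pass; a two-stage
`per_algorithm` mode (average each algorithm's runs, then weight by mean
TSS) is available as a config option — the two agree in expectation.

## Masking, ranking and the two filters

The probability raster is masked to the broadleaved woodland categories
(`broadleaved` and `mixed` in the synthetic landscape): pixels outside are
set to zero and marked ineligible. Eligible pixels are ranked from highest
to lowest probability with ties broken by (row, col) ascending, so every
selection is bit-reproducible.

**Area filter.** Ranked pixels are accumulated "up to" the published
regional stocked-oak area: the selection is the largest prefix whose area
does not exceed the target (`n = max{k : k × 0.25 ha ≤ target}`); a
`round_nearest` mode rounds the pixel count instead. If the eligible pool
is smaller than the target, everything is selected and the shortfall
recorded.

**Elevation filter.** Pixels are binned into half-open 10 m elevation
classes ([0, 10), [10, 20), …) by the DEM value at the pixel centre. The
survey histogram is first rescaled to the regional pixel target with
largest-remainder rounding (exact total, proportions preserved); then each
class quota is filled with that class's highest-ranked pixels. Classes
with too few eligible pixels take all they have and record the deficit —
quotas are never reallocated across classes, because reallocation would
distort precisely the distribution the filter exists to impose. Within
each class the selection is provably optimal (top-k by probability), which
the tests confirm against exhaustive enumeration on small inputs.

**Manual adjustment diagnostic.** Setting the probability of known
training oak pixels to 1 before filtering should change almost nothing if
the model already ranks them at the top; `manual_adjust_check()` reports
the signed mean difference `mean(1 − p)` over training pixels, and a flag
(`adjust_before_filter`) applies the adjusted raster to the filters.

**Distribution comparison.** The probability values of the two selections
are compared with a two-sample Kolmogorov–Smirnov test (asymptotic
p-value). Forcing pixels into the survey's elevation distribution drags
the selection into lower-probability pixels, so the elevation-filtered
selection develops a heavier low-probability tail; the KS statistic
quantifies that separation.

## Validation statistics

A validation site counts as coincident when at least one selected pixel
centre falls inside it (any-overlap; a documented choice — the convention
is not derivable from the method itself, and a buffered variant would be
needed for point-located sites). The coincidence rate is the model's true
presence rate (sensitivity). It is reported with:

* an exact Clopper–Pearson interval from the beta-quantile construction
  (`qbeta(α/2, x, n−x+1)` and `qbeta(1−α/2, x+1, n−x)`, with exact 0/1
  endpoints at the boundary counts). Clopper–Pearson is used rather than
  Wilson because the exact construction is the one that reproduces the
  published rounded bounds for both worked examples (42–67% for 35/64 and
  71–91% for 53/64); Wilson gives 43% for the first lower bound.
* a two-sided exact binomial test against a null proportion p0. The
  default p0 = 0.5 (no better than a coin flip per site) is the unique
  round null that reproduces the published p-value 0.5323 for 35 of 64,
  which we verified against a direct minimum-likelihood tail-sum oracle;
  it is exposed as a parameter.

## The synthetic landscape

The generator produces every input the pipeline needs, with the
statistical structure the method assumes. Defaults below are the study
conditions used by the analysis scripts and tests.

| parameter | default | meaning |
|---|---|---|
| grid | 200 × 200 px of 50 m | 10,000 ha landscape, 0.25 ha pixels |
| regions | 3 vertical bands | independently fitted reporting regions |
| DEM | smoothed Gaussian field, mean 250 m, sd 160 m, range ~8 px | spatially autocorrelated terrain |
| AT | 1850 − 1.8·DEM + noise (dd > 5 °C) | accumulated temperature, lapse with elevation |
| CMD | 190 − 0.45·DEM + noise (mm) | moisture deficit, decreasing with elevation |
| DAMS | 7 + 0.018·DEM + noise | wind exposure, increasing with elevation |
| TWI, SMR, SNR | independent smooth/ordinal fields | wetness and soil regimes |
| stands | 5–30 ha, banded-serpentine tessellation | subcompartment polygons on pixel edges |
| niche | logit with quadratic AT term | oak optimum at intermediate elevation |
| `occupancy_area_fraction` | 0.12 | oak share of the landscape |
| `management_bias` | 150 m | elevation displacement of occupancy |
| `occupancy_noise_sd` | 1.0 (logit) | unmeasured land-use history per stand |
| `estate_skew` | 1.0 | training stands suitability-typical |
| `validation_fraction` | 0.25 | occupied stands withheld as sites |
| `sample_fraction` | 0.1 (pipeline), 0.006 (function default) | survey-plot share of occupied area |

Three deliberate mechanisms give the landscape the structure the filters
are designed to exploit:

* **A non-monotone elevation profile.** The niche logit includes a
  quadratic accumulated-temperature term. This matters: with a purely
  linear logit, every covariate is linear in elevation, so an additive
  elevation offset shifts the logit by a constant and leaves the ranking
  of stands — and therefore which stands are occupied — unchanged. An
  intermediate-elevation optimum (ecologically realistic for oak) is the
  minimal structure under which a management displacement is visible at
  all.
* **Management displacement plus scatter.** The occupancy score is the
  suitability logit evaluated as if each stand sat `management_bias`
  metres higher (through the deterministic covariate lapses), plus
  stand-level Gaussian noise (`occupancy_noise_sd`) representing land-use
  history no site variable records. With bias and noise both zero,
  occupied stands are exactly the top-suitability stands.
* **An estate-vs-survey population split.** Training presences come from
  the stand map's "estate", chosen with a skew towards
  suitability-typical occupied stands; validation sites are the withheld
  remainder (each represented by a 1 ha footprint at the stand centroid,
  the plot-scale convention of site databases), and the elevation
  histogram is sampled from all occupied stands. This reproduces the
  situation where the model trains on one well-mapped subpopulation but
  is deployed and validated against the full oak population.

Under these conditions the area-only filter under-selects the displaced
oak and the elevation filter recovers it — the direction of improvement
the method exists to demonstrate — while with `management_bias = 0` the
two filters perform statistically indistinguishably. The acceptance
script (`scripts/acceptance.R`) recomputes both rates end to end.

What the generator does **not** emulate: real terrain, geology or climate
fields (no coordinate reference systems beyond a tag, no anisotropy, no
coastlines); mapping error in polygon boundaries or species attributes;
survey measurement error in the histogram beyond sampling noise;
spatial autocorrelation of model residuals (no spatial-block
cross-validation is implemented, as none is used in the method); and
multi-species composition dynamics. Passing tests on this landscape show
the pipeline's logic is correct and its statistics exact; they do not show
that four learners and two filters suffice for any particular real
inventory.

## Numerical choices

* All randomness is seeded; per-run learner seeds are derived from the
  stage seed, xgboost runs single-threaded and ranger receives an explicit
  seed, so ledgers and rasters reproduce bit for bit.
* Threshold grid step 0.01; smallest-threshold tie-break.
* Area accumulation uses `floor(target/0.25 + 1e-9)` — the epsilon guards
  exact multiples against floating-point descent.
* Histogram rescaling uses largest-remainder rounding (exact totals).
* Degenerate inputs fail loudly: empty classes in TSS, empty site lists,
  off-grid training pixels, infeasible occupancy fractions and absence
  pools smaller than the presence set are all errors, not warnings.
* The elevation histogram sample is drawn as survey plots (pixels) across
  occupied stands. At a 10,000 ha demonstration scale the national 0.6%
  area fraction would amount to a single stand per region, which cannot
  populate 10 m classes; the pipeline default of 10% keeps the per-class
  sampling error at the demonstration scale comparable to a national
  survey's at full scale. The function default remains 0.6%.

## Problem sizes

The analysis scripts run the full design (15 replicates × 30 repeats per
region, 1,800 evaluations per region) on the 200 × 200 landscape. The test
suite exercises the same code at reduced repeat counts, and the acceptance
script runs the end-to-end pipeline with 6 repeats — demonstration scales
chosen so the whole suite runs comfortably on one CPU while leaving every
structural count (4 algorithms, 15 replicates, prevalence 0.5) at its
design value where it is the object under test.

## Limitations

* The coincidence rule, threshold rule and per-run weighting are
  documented conventions, not derivable facts; alternatives are exposed
  as options where they matter.
* Regional models are independent; no information is shared across
  regions, and a region without presence stands is skipped.
* The area target is taken at face value (the published totals include
  mixed stands; the presence definition is 60% canopy — the method does
  not attempt to reconcile the two definitions).
* Shortfalls in elevation classes are reported, never reallocated, so the
  elevation-filtered area can fall short of the regional target when the
  eligible pool is thin in some classes.
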