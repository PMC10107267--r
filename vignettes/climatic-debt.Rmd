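---
title: "Measuring community thermophilization and climatic debt from presence-only records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community thermophilization and climatic debt from presence-only records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the estimator

As climate warms, local assemblages gradually exchange cold-adapted for
warm-adapted species. With abundance-structured monitoring data this
*thermophilization* is classically tracked through the community temperature
index (CTI), an abundance-weighted mean of species' thermal affinities.
Opportunistic occurrence records — the bulk of what public biodiversity
databases hold for most animal groups — carry no abundance information, so
`ctidebt` implements the presence-only variant of the whole chain:

1. **Species temperature index (STI).** For species $s$, the mean temperature
   extracted at all of its cleaned, spatially thinned occurrences, each
   matched to the 5-year period mean temperature at its location:
   $\mathrm{STI}_s = \frac{1}{n_s}\sum_{i} T(x_i, p_i)$.
2. **CTI.** For a window $w$ and period $p$ with species set $S_{wp}$
   (at least two species),
   $\mathrm{CTI}_{wp} = \frac{1}{|S_{wp}|}\sum_{s \in S_{wp}} \mathrm{STI}_s$ —
   an unweighted mean over the distinct species present.
3. **CTI trend.** A weighted linear mixed model
   $\mathrm{CTI}_{wp} = \beta_0 + \beta_1\,\mathrm{year}_p + \beta_2\,\bar T_w
   + \text{continent} + (a_w + b_w\,\mathrm{year}_p) + e_{r(w)} +
   \varepsilon_{wp}$,
   with a random intercept and year slope per window, a random intercept per
   ecoregion, and weights $\log n_{wp}$ (the thinned occurrence count).
   The *local CTI trend* of window $w$ is $\beta_1 + b_w$.
4. **Climatic debt.** A second weighted mixed model regresses the local CTI
   trends on the local temperature trends $b_{T,w}$ (OLS slope of window
   period-mean temperature on period median year), in interaction with the
   window's mean temperature (centred) and with the human influence index
   (HII), with continent and an ecoregion random intercept. The marginal
   slope at a given HII value $h$ is
   $\beta_{b_T} + \beta_{b_T \times \bar T}\cdot 0 + \beta_{b_T \times
   \mathrm{HII}}\, h$, with Wald CIs from the coefficient covariance.
   A slope of 1 means communities track temperature change completely;
   a slope below 1 is the climatic debt.
5. **Turnover.** Species gained and lost between consecutive periods carry a
   relative STI, $\mathrm{rSTI} = \mathrm{STI}_s - \mathrm{CTI}_{w,t-1}$,
   separating warm-adapted (positive) from cold-adapted (negative)
   colonisations and losses.
6. **Meta-analysis.** Per-taxon estimates are pooled by DerSimonian–Laird
   random-effects meta-analysis (`metafor::rma`, method `"DL"`).

## Data handling conventions

* **Cleaning.** Records at exactly (0, 0), with latitude equal to longitude,
  within a configurable radius (default 1 km) of listed capital/country
  centroids or institutions, or on non-land cells are removed. All rules are
  evaluated against the raw table, so rule order cannot change the survivor
  set.
* **Periods.** 1990–2019 in six 5-year periods indexed 0–5; the median year
  (start + 2) is the time coordinate. For December–January (winter) taxa,
  December is grouped with the following January — one biological winter —
  and the pair belongs to the January's period; December of the final study
  year therefore has no study winter and is dropped. The same convention
  builds the winter period temperature rasters.
* **Thinning.** One record per species per 5 km × 5 km cell per period,
  chosen uniformly at random under an explicit seed. The grid lives in the
  world cylindrical equal-area projection (authalic radius), because "5 km"
  is a metric statement; a degree grid would shrink with latitude.
* **Windows.** Buffers of radius 200 km around the centres of a 1° lattice;
  membership is geodesic (haversine). Windows overlap by construction.
  A window's ecoregion is the region with the largest land area
  (cosine-latitude-weighted cell count) inside the buffer; window climate
  covariates are unweighted means over land cells whose centres fall in the
  buffer (area weighting would change values by well under the climate
  grid's cell-to-cell variation at these latitudes).
* **Missing months** are kept for all-month taxa (season membership is
  irrelevant) and dropped for seasonal taxa (membership is undecidable).
* **Weights.** The natural log of occurrence counts. Any other log base
  rescales all weights by a constant, which leaves weighted least-squares
  estimates unchanged — a property the test suite checks directly.
* **Assemblage qualification.** A CTI value exists for every window × period
  with at least two STI-bearing species; a window is retained when at least
  one of its periods qualifies. The alternative reading (threshold on the
  window's pooled species list) is available via
  `compute_cti(..., qualify = "window")`.
* **Year centring.** Median years are centred at 2004.5 before fitting;
  this conditions the random-slope model and does not change the slope.
* **Estimation.** REML throughout; Wald 95% CIs on fixed effects. If the
  crossed window × ecoregion fit fails, the model is refitted with ecoregion
  as a fixed factor and the fallback is recorded in the fit metadata.

## The synthetic world

Real analyses of this kind rest on multi-gigabyte occurrence downloads that
cannot be redistributed or reprocessed at desk scale, so validation uses a
generative world in which every quantity the pipeline estimates has a known
true value.

* **Landscape.** Two rectangular continents (14.5° of longitude each)
  separated by a 5° sea channel, on a 0.5° grid spanning 38–60° latitude.
  Monthly temperature is `baseline(lat) + seasonal(month) + w(cell) × (year −
  1990)` (+ optional noise): a 0.6 °C/deg south–north gradient, a +1 °C
  offset on the eastern continent, an 8 °C seasonal amplitude.
* **Warming.** Either uniform or a per-continent longitudinal ramp spanning
  0–0.04 °C/yr across the window lattice. The ramp is linear in longitude
  and the lattice keeps 3° away from continent edges, so every 200-km buffer
  sees a locally linear warming field and is never truncated: the buffer-mean
  temperature trend then equals the trend governing the assemblage response,
  and the debt-model slope has a clean expectation. (Margin cells extrapolate
  the ramp slightly beyond the nominal range; they are outside every
  buffer-mean.)
* **Ecoregions.** A mosaic of 2° × 2° rectangular blocks per continent.
  Blocks at the scale of the window buffers let the ecoregion random
  intercepts absorb mesoscale spatial structure shared by overlapping
  windows; broad latitudinal bands were tried first and left the model
  standard errors overconfident.
* **Species.** 4000 species with Gaussian thermal niches (σ = 0.8 °C,
  plateau occupancy 0.9), optima uniform over the thermal band reachable
  from the window lattice plus a presence margin — so assemblages are never
  truncated by the edges of the pool. Cell-level presence compares the
  occupancy probability with a persistent uniform threshold per (species,
  cell): period-to-period composition change is then driven by temperature
  change, not by independent re-draws of occupancy.
* **Tracking.** Each species responds to a *perceived* temperature field,
  `T(1990) + λ (T(t) − T(1990))`, with λ ∈ [0, 1] the tracking fraction,
  optionally declining with anthropization as `λ (1 − h · HII/64)`. By
  construction the expected debt-model slope is λ, and the HII interaction
  is negative when `h > 0`.
* **Sampling.** Presence-only records are drawn from occupied cells with
  effort growing by a factor 1.2 per 5-year period (75,000 expected records
  in the first period; public-database effort grows exponentially) and a
  spatial bias `exp(HII/64)` towards anthropized areas; coordinates are cell
  centres jittered within the cell; provider labels follow a configurable
  categorical distribution with an "unknown" mass, as in real aggregated
  data.

These defaults produce ~750,000 records over 108 windows and are the
conditions under which the validation experiments run. The scaled-down
configuration used by most tests (48 windows, 800 species, ~120,000 records)
keeps full-pipeline checks below a few seconds each.

### What the generator does and does not emulate

It reproduces the features the method must survive: spatially biased and
exponentially growing effort, unknown providers, presence-only information,
overlapping windows, a human-influence surface confounded with sampling
intensity. It does not attempt demographic realism — no dispersal limits,
population dynamics, detection submodels, abundance structure, taxonomic
error, or coordinate noise beyond within-cell jitter. Passing tests
therefore show that the estimators recover known community-level parameters
from realistic presence-only sampling; they do not show robustness to
misidentification or to abundance-driven artefacts, which presence-only CTI
cannot see by construction.

## Validation experiments and known limitations

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` recompute, from scratch:

* λ = 1 with heterogeneous warming → marginal debt slope at median HII
  near 1 (the headline experiment, 20 replicates at the default scale);
* λ = 0.5 → slope near 0.5; λ declining with HII → smaller marginal slope
  at the 75th than at the 25th HII percentile;
* the fitted CTI time trend against an occupancy-based oracle that computes
  the expected CTI drift directly from the generator's probabilities;
* exact identities: CTI as a brute-force mean, the turnover decomposition
  `CTI_t − CTI_{t−1}` reconstructed from gains and losses, the thinning
  count bound, and temperature trends on noiseless fields.

Two properties of the two-stage procedure deserve emphasis, because the
validation experiments expose them rather than hide them. First, local CTI
trends are BLUPs: shrinkage towards the fixed slope attenuates the debt
slope multiplicatively by a factor that approaches 1 only as sampling
density grows — at the default scale the mean recovered slope under λ = 1
sits a percent or two below 1. Second, overlapping windows share records,
species and occupancy realisations, so local-trend errors are correlated
across windows (including along isotherms, across ecoregion boundaries);
the debt model's Wald CI, which conditions on the fitted random-effect
structure, understates replicate-to-replicate variability somewhat even
with the block ecoregion mosaic. Both effects are inherent to the design
(window overlap is what makes presence-only assemblages big enough to use),
and both also apply to real-data analyses of this type: reported debt
slopes are conservative, and their nominal CIs are somewhat narrow.

## A worked run

```{r example}
library(ctidebt)

world <- simulate_world(world_config(seed = 1))
run <- analyze_world(world)

run$trend_fit          # CTI warming trend with 95% CI
run$debt_fit           # marginal debt slopes at HII quartiles

ev <- turnover_events(run$pipeline$cti, run$pipeline$assemblages,
                      run$pipeline$sti)
summarize_turnover(ev, n_boot = 1000, seed = 1)

# pool several taxa
meta_analyze(c(0.0226, 0.0179, 0.0095), c(0.0009, 0.0005, 0.0014))
```
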