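---
title: "Methods: from microcosm images to density-dependent demography and a survival-strategy index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microcosm images to density-dependent demography and a survival-strategy index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microcosmr` implements a complete inference chain for protist microcosm
experiments that ask how density-dependent demography relates to movement and
morphology traits under crossed environmental drivers (temperature x
pollutant). Because raw experimental videos are bulky and rarely shipped with
analysis code, the package pairs every analysis stage with a synthetic
generator that emulates the measurement process, so the whole chain is
testable end to end against known ground truth.

```{r setup, message = FALSE}
library(microcosmr)
```

## The demographic model

Each microcosm population follows logistic density dependence,

$$\frac{dN}{dt} = N(\mu + \alpha N),$$

with intrinsic per-capita growth rate $\mu$ (per day) and conspecific
interaction coefficient $\alpha$ (per day per cell/mL, negative under
self-limitation). `grow_population()` integrates this in closed form. A
dilution assay observes several starting densities of the same population
over a short interval; the per-capita growth rate

$$\mathrm{pcgr} = \frac{\ln(N_\mathrm{end}/N_\mathrm{start})}{t_\mathrm{end}-t_\mathrm{start}}
\approx \mu + \alpha N_\mathrm{start}$$

is then regressed on starting density (`fit_curve()`), one pooled ordinary
least squares per condition over all replicate assays (15 points with the
default 5 dilutions x 3 replicates). Pooling replicates into a single curve
maximizes the precision of the two coefficients when the predictor is
continuous. Carrying capacity is the derived ratio $K = -\mu/\alpha$
(`carrying_capacity()`), with variance from the first-order Taylor (delta
method) expansion of a ratio of correlated estimators:

$$s^2\!\left(\tfrac{-\mu}{\alpha}\right) \approx
\frac{\bar x_\mu^2}{\bar x_\alpha^2}\left(\frac{s^2_\mu}{\bar x_\mu^2}
- 2\frac{\mathrm{cov}(\mu,\alpha)}{\bar x_\mu \bar x_\alpha}
+ \frac{s^2_\alpha}{\bar x_\alpha^2}\right).$$

The approximation is first order, and its error against brute-force Monte
Carlo grows with the square of $\alpha$'s coefficient of variation
(roughly $8\,\mathrm{CV}_\alpha^2$ in relative terms, nearly independent of
the $\mu$–$\alpha$ correlation): it stays within 5% while
$\mathrm{CV}_\alpha \lesssim 8\%$, reaches about 8% at
$\mathrm{CV}_\alpha = 10\%$, and degrades rapidly beyond as the ratio
distribution develops heavy tails. `benchmark_k_variance()` maps that
envelope for any estimator moments; report $s^2_K$ with it in mind.

### Interval selection

With three sampling occasions per microcosm, growth over the first interval
can be too small to measure precisely. `select_interval()` operationalizes
the choice deterministically: scan t0->t1, t0->t2, t1->t2 in that order and
take the first whose observed density fold-change reaches `min_fold_change`
(default 1.5); if none qualifies, take the candidate with the largest
fold-change. The chosen interval is recorded per microcosm and re-used,
unchanged, for the trait responses, so demography and trait change are
always measured over the same window.

### Influence screening

Individual pcgr points can be corrupted by a failed assay or a sampling
error. `exclude_influential()` removes a point only when two diagnostics
agree: Cook's distance at or beyond `cooks_threshold` (default 0.5, the
"border" contour drawn on standard regression diagnostic plots; the 1.0
contour is one config change away) *and* an externally studentized residual
of magnitude at least `resid_threshold` (default 2). At most
`max_exclusions` (default 2) points are removed per curve — most extreme
first — and the curve is refit exactly once. The dual requirement is what
keeps high-leverage but on-line points and central noisy points in the data;
only points that are both influential and discrepant go. Excluded points
remain part of the trait dataset: a bad density estimate does not invalidate
the trait measurements of the same sample.

K estimates below `k_min_valid` (default -400 density units) are flagged
invalid: such values arise when the fitted $\alpha$ is positive (growth
increasing with density), where a carrying capacity is not meaningful. They
are excluded from K-level analyses but their conditions keep contributing to
$\mu$ and $\alpha$.

## The synthetic experiment

The generator's default conditions describe a two-species experiment:
2 species x 3 strains x 3 temperatures (20/22/24 °C) x 3 atrazine levels
(0/10/20 µg/mL), three replicate dilution assays per condition, five
dilutions (20-80% source culture), three time points, and 100-frame
dark-field bursts at 10 frames/s covering 810 µL. That layout yields exactly
54 conditions (curves), 162 assays, 810 sample pairs, 2430 picture series
and 15 points per curve — `design_counts()` reproduces these as integer
arithmetic.

Quantities the design does not fix were chosen once, as an assay-design
exercise, and then frozen:

* **Species scales.** Species A is a Colpidium-like large, slow ciliate
  ($\mu$ = 1.2/day, K = 10^4 cells/mL); species B a Tetrahymena-like small,
  fast one ($\mu$ = 2.0/day, K = 5x10^4 cells/mL). Strains within a species
  differ modestly in $\mu$ (+-0.1/day), $\alpha$ (+-10%) and trait baselines.
* **Sampling schedule.** Time points are spaced 0.2 day (species A) and
  0.1 day (species B) apart. A pilot simulation over candidate schedules
  showed why short intervals matter: the pcgr regression is the
  *short-interval linearization* of the logistic model, and once a
  population grows severalfold within the measured window the time-averaged
  density exceeds $N_\mathrm{start}$ enough to bias $\hat\alpha$ upward in
  magnitude by 20% and more, regardless of counting noise. Keeping expected
  fold-changes near or below the 1.5 precision threshold puts the estimator
  in the regime it was derived for, with the fallback rule then selecting
  the widest window — exactly the design logic of a dilution assay, which
  trades growth signal against linearization error.
* **Counting noise.** Observed densities are counts in the imaged 810 µL,
  Poisson around `true density x volume` with 2% extra relative dispersion
  (gamma-Poisson mixing). The overdispersion stands in for cells clustering
  during sampling despite mixing; it also dominates the Poisson
  heteroscedasticity at high counts, which keeps the homoscedastic OLS
  confidence intervals close to nominal.
* **Traits.** Each cell draws a fixed (speed, linearity, size, shape) from
  the strain's treatment- and crowding-adjusted means; within-sample
  variance is plasticity among cells, not within-track fluctuation. Trait
  means shift weakly with temperature and pollutant and with crowding
  (density change relative to K): growing populations drift towards the
  flee phenotype — faster, straighter, smaller, more elongated. The
  magnitudes are free parameters of the generator, documented in
  `default_strain_profiles()`, not estimates of any real species.
* **Movement.** Cells are correlated random walks: constant step length
  `speed / frame_rate`, turning angles von Mises with concentration mapped
  from the linearity trait by inverting the mean-cosine function
  (`linearity_to_kappa()`). Walkers reflect at the arena border.
* **Imaging.** Dark-field frames are 8-bit, near-black background with
  Gaussian sensor noise, each cell a filled bright ellipse at its per-frame
  position and heading (`render_frames()`). Origin is top-left, x right,
  y down, positions in pixels, frames 0-based, times `frame/frame_rate`.

What the generator does *not* emulate: bacterial resource dynamics and medium
chemistry, toxicokinetics of the pollutant, cell division or death within a
burst, out-of-focus blur, illumination gradients, and imaging artefacts that
mimic cells. Passing tests therefore demonstrate correctness of the
*analysis chain* under a faithful observation model, not robustness to every
failure mode of real videos; the quality-control layers (trajectory QC,
influence screening, K validity) exist precisely for those real-data
pathologies and are exercised on engineered fixtures instead.

## Tracking

`detect_particles()` thresholds each frame at `grey_threshold`, labels
connected components, and keeps those whose pixel area and moment-matched
ellipse aspect ratio (normalized major/minor >= 1) fall inside configured
bounds. `link_particles()` associates detections across frames under a
per-frame step constraint (`max_step`) with gap bridging up to `max_gap`
missed frames. The default linker is greedy nearest-neighbour with a fully
deterministic tie-break (distance, then track id, then scan order), which
makes output canonical and order-invariant; an exact minimum-total-distance
assignment (`method = "optimal"`) is available for robustness checks at low
particle counts.

Per-trajectory metrics follow the standard conventions: gross displacement
is the summed step length (bridged linearly across gaps), net displacement
the straight line start to end, speed = gross/duration. **Linearity is
net/gross in [0, 1]**, so 1 means a straight path — the convention under
which "high linearity" reads as directed movement. The reciprocal
(gross/net) phrasing found in some protocol descriptions is available as
`linearity_convention = "gross_over_net"` for exact-wording compatibility,
but the net/gross form is what enters the strategy index. Quality control
(`qc_filter()`) discards tracks below minimum duration, net displacement or
detection frequency, recording which criterion failed; defaults are
species-agnostic and deliberately permissive, since real pipelines tune
them per species. Density is QC-passing trajectories per imaged volume;
traits are averaged over trajectories within a sample (the population
level), with unbiased variances.

## The survival-strategy index

Traits are standardized at the species level over all sample-level trait
means from time points contributing to the curves
(`fit_standardization()`; pool statistics are frozen before any response is
computed), then combined with equal weights:

$$\mathrm{index} = z(\mathrm{speed}) + z(\mathrm{linearity})
- z(\mathrm{size}) + z(\mathrm{shape}),$$

low = sit-and-wait, high = flee. The response per microcosm is the change in
the index's sample mean and variance over the same interval as growth
(`index_response()`).

How within-sample trait variances combine into a "variance of the index" is
genuinely open. The default treats traits as independent within a sample, so
the index variance is the sum of species-scaled trait variances (weights are
all +-1); the alternative `per_trajectory_index()` computes the index per
trajectory and takes moments across trajectories, which captures trait
correlations at the cost of requiring per-trajectory data. Neither is
claimed canonical; both are exported.

## Driver models and linkage

`demography_anova()` fits, per species, the factorial fixed-effects model of
pcgr with starting density as covariate: factor terms express differences in
$\mu$, their interactions with starting density differences in $\alpha$.
Sums of squares are sequential (Type I) in the fixed printed order —
the default of the common analysis environments for `anova()` on a fitted
linear model — with a Type III option behind `ss_type` since balanced
designs make main effects agree anyway and real datasets may not be
balanced. Temperature and pollutant are categorical (2 df each), giving the
2/2/2/4/4/4/8 df pattern. Every term carries partial eta squared
$SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{residual})$.
`index_anova()` does the same for the index responses without the covariate.
Replicate does not enter as a factor; it is carried as bookkeeping only.

`build_condition_records()` reduces everything to one record per condition:
demographic parameters z-standardized within species ($\mu$ and $\alpha$
over all 27 conditions of a species; K over its valid conditions only) and
index responses averaged over replicates and dilutions. `fit_linkage()` then
compares 15 linear-model variants per demographic response — a Null model
and, for each predictor ($\Delta$mean, $\Delta$variance), seven
intercept/slope structures: common, per strain, or per strain of one species
with the other species pooled (`strainC`/`strainT`, realized as a 4-level
factor so a single design matrix reproduces the pooled-coding semantics).
Model ranking uses the small-sample Akaike criterion

$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k$ counting all mean coefficients plus the residual variance. The
additive normal-likelihood constant is dropped; since every comparison is
within one response column, rankings are unaffected, and the convention is
stated so numbers can be compared across implementations. Ties below 1e-9
break towards fewer parameters, then the fixed variant order. $\Delta$mean
and $\Delta$variance families are kept separate, and no multimodel averaging
is performed — a single best model per response.

## Numerical choices and degenerate inputs

* Logistic closed form used everywhere (no step integration); $\alpha = 0$
  and $\mu = 0$ branches handled analytically.
* Zero-count densities are unusable for pcgr; microcosms with fewer than two
  usable time points are dropped with a logged reason.
* Rank-deficient curves (fewer than 3 points or fewer than 2 distinct
  starting densities) raise errors naming the condition.
* A zero-gross track has linearity 1 by convention (a stationary cell is
  "straight"); single-detection tracks have undefined metrics and fail QC.
* Constant traits in a standardization pool raise an error naming the trait
  rather than silently dividing by zero.
* All randomness flows through R's global RNG: one seed in
  (`design_config(rng_seed=)`, `run_pipeline(seed=)`) makes every stage
  bit-reproducible.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full design arithmetic
(54/162/810/2430), parameter recovery on 200 simulated curves, a 10^6-draw
Monte Carlo check of the K variance, tracking fidelity on ten rendered
100-frame stacks of 20 walkers (512 x 512 px), and linkage model recovery
over 200 simulated 54-record datasets. These sizes were chosen as the
smallest that pin down the statistical properties being claimed (medians,
coverage, selection frequencies) with comfortable Monte-Carlo margins.

## Known limitations

* The greedy linker can swap identities when two cells cross closely;
  density and population-level trait summaries are insensitive to swaps,
  but individual-level longitudinal analyses would not be.
* Detection merges overlapping cells into one blob; at the benchmark's
  occupancy (~2%) this costs a few detections per burst and is bridged by
  gap handling, but crowded samples would need occlusion-aware tracking.
* The delta-method K variance is a first-order approximation; report it
  with its validity region (CVs below ~10%) in mind.
* The pcgr regression inherits the classic linearization trade-off
  described above: long measurement windows bias $\hat\alpha$. The package
  measures and documents the regime; it does not correct the bias.
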