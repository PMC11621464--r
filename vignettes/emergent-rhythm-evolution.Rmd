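---
title: "Quantifying and comparing the evolution of collective and individual activity rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing the evolution of collective and individual activity rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Social insect colonies are a textbook case of emergence: workers inside a
nest activate in synchronized ultradian bursts — rest/activity cycles with
periods of tens of minutes to a couple of hours — that no isolated worker
expresses in the same form. If a collective trait like the regularity of
these bursts is shaped by social interaction rules and not just by the
intrinsic clocks of individual workers, its evolutionary dynamics across
species can decouple from the dynamics of the matching individual-level
trait: it can evolve faster, diversify more, and show no evolutionary
correlation with its individual counterpart. `rhythmevo` implements the
full analysis chain needed to test that hypothesis, from image-derived
activity extraction through wavelet rhythm metrics to phylogenetic
comparative inference, together with a synthetic-data module that makes
every stage verifiable against known ground truth.

This vignette records the package's methodological choices: the models and
their assumptions, the parameters that matter and their defaults, what the
synthetic generator does and does not emulate, and the numerical decisions
a maintainer would want written down.

## The analysis chain

1. **Activity extraction** (`pixel_change_activity()`,
   `optical_flow_activity()`, `centroid_displacement_series()`,
   `open_field_speed()`): image sequences become one activity value per
   30 s frame transition; open-field videos become walking speeds in
   body-lengths per second.
2. **Rhythm metrics** (`rhythm_metrics()`): each series is rescaled to
   [0, 1], smoothed with a 15-point Gaussian moving average, transformed
   with a continuous wavelet transform, and summarized by its dominant
   period and coherence factor.
3. **Tip values** (`species_tip_values()`): per-recording metrics collapse
   to one value per species and trait through a linear mixed model.
4. **Evolutionary inference** (`bootstrap_rate_comparison()`, `pgls()`,
   `sensitivity_pgls()`, `disparity_comparison()`): Brownian-motion rates
   with a bootstrap rate test, phylogenetic regression between levels, and
   multivariate phenotypic disparity.

`run_study()` sequences all stages under one configuration and master seed;
the numbered scripts under `analysis/` drive the same functions as a
narrative workflow.

## Rhythm quantification

**Processing order.** Rescale → smooth → transform, fixed. Rescaling first
makes the coherence factor invariant to the amplitude and units of the raw
signal (pixel proportions, flow magnitudes, and centroid displacements all
land on a common footing). Smoothing before the transform is essential:
high-frequency measurement noise otherwise contaminates the periodogram and
distorts both metrics. The smoothing kernel is a Gaussian over a 15-point
centered window with `sd = (window - 1) / 5` points (the convention of the
common signal-processing `gausswin` family at its default shape parameter);
at the study's 30 s sampling this is a 7.5-minute window, far below the
10–120 min periods of interest. Edges use truncated, renormalized kernels
so the series length is unchanged.

**Wavelet periodogram.** `wavelet_periodogram()` computes an analytic
Morlet transform (center frequency `omega0 = 6`) on a logarithmic scale
grid with 12 voices per octave spanning periods from twice the sampling
interval to half the record length. The transform is FFT-based with
reflection padding to soften edge effects; no cone-of-influence exclusion
is applied — the absolute coefficient magnitudes at each scale are summed
over *all* time points, giving the total power per oscillation period. Both
metrics derive from this summed profile:

- **dominant period** — the period at the global maximum (ties broken
  toward the shorter period, deterministically);
- **rhythmicity** — the coherence factor
  $\beta = H_{dp} / W_m$, the ratio of the tallest peak height to the mean
  wavelet magnitude. A flat periodogram gives exactly 1; $\beta$ can never
  fall below 1 because a maximum is never below the mean. It behaves as a
  signal-to-noise ratio for rhythm regularity and, because it is a ratio of
  magnitudes from the same transform, it is robust to the choice of
  analytic mother wavelet.

Colony recordings (14.5 h) are truncated to the individual recording length
(8.5 h) before metric computation wherever the two levels are compared, so
series of equal length enter the comparison. Truncation keeps the *head* of
the series: recordings start in the morning, so the first frames are the
common window. For the stationary synthetic generator the choice is
immaterial (a property the test suite checks); for real data with
nonstationary afternoons it would matter, which is why the choice is
documented rather than silent.

## Tip values and the mixed model

Species differ in how many colonies were sampled and colonies are recorded
twice, so a species mean over recordings would weight colonies unevenly and
ignore the colony-level variance component. For each trait and level the
package fits
$y_{ij} = \mu_{s(i)} + b_{c(i)} + \varepsilon_{ij}$ with species as
cell-means fixed effects and colony of origin as a random intercept,
estimated by REML; the species coefficient $\hat\mu_s$ is the tip value.
The implementation profiles the REML criterion down to a one-dimensional
optimization over the variance ratio
$\lambda = \sigma_b^2 / \sigma_e^2$ (log-scale search on
$[e^{-12}, e^{12}]$ plus the $\lambda = 0$ boundary, tolerance $10^{-6}$),
which makes a fit cheap enough to sit inside bootstrap loops; the unit
tests verify exact agreement with `lme4::lmer` on unbalanced designs. With
one recording per colony the estimates degrade gracefully to species means,
and a degenerate residual variance (constant trait) short-circuits to the
same closed form.

## Evolutionary inference

**Rate of evolution.** Under Brownian motion on a chronogram, tip values
are multivariate normal with covariance $\sigma^2 C$, where $C_{ij}$ is the
shared root-to-tip path length. `fit_bm()` uses the closed-form maximum
likelihood estimates (GLS root state; $\hat\sigma^2$ with the $n$
denominator, matching the default behavior of the standard comparative
methods tools). The estimator's $(n-1)/n$ bias and its exact branch-length
scaling law $\hat\sigma^2(c\,T) = \hat\sigma^2(T)/c$ are both asserted in
the tests. Before any rate comparison each trait is standardized by
dividing every tip value by the cross-species trait mean, so rates are
comparable across traits with different units; the standardization is
recomputed inside every bootstrap replicate.

**Bootstrap rate comparison.** The sampling unit is the colony (with both
its recordings) at the colony level and the individual at the individual
level — resampling respects the grouping structure the mixed model assumes,
and resampling to the original counts within each species means no species
can drop out of a replicate. Replicates are paired across levels by common
random numbers: the same uniform draws select the units at both levels, so
two literally identical input tables yield a rate difference of exactly
zero in every replicate, and the paired difference is sharpened in general.
The one-sided p-value is the proportion of replicates in which the
colony-minus-individual rate difference fails to exceed zero, floored at
$1/n_{boot}$ — with the default 10,000 replicates the smallest reportable
p-value is 0.0001.

**PGLS.** `pgls()` regresses one level's tip values on the other's with
residual covariance proportional to $C$, solved by generalized least
squares; the slope's $t$ statistic is referred to Student's $t$ with
$n - 2$ degrees of freedom. On a star phylogeny this reduces exactly to
ordinary least squares, and on arbitrary trees it agrees with a
Cholesky-whitening oracle to $10^{-10}$ (both asserted). The sensitivity
analysis redraws every species' x and y values from
$\mathrm{Normal}(\text{tip value}, \text{intraspecific SD})$ and refits;
the summary p-value is the **median** across iterations. Median was chosen
as the aggregation because it is the natural robust summary of a p-value
distribution under measurement perturbation; the full distribution is
returned so any other summary can be computed.

**Disparity.** The phenospace has two axes — rhythmicity and dominant
period (walking speed is carried through tip values descriptively but does
not enter the phenospace). Both levels' point clouds are jointly
standardized per axis (pooled z-score across the two levels), which keeps
the spaces comparable while preserving their relative extents; disparity is
the sum of per-axis variances ($n - 1$ denominator) across species. The
bootstrap resamples species rows within each level independently and the
one-sided p-value uses the same floor convention as the rate test. Joint
standardization and independent within-level resampling were genuinely open
choices; both are pinned down here and exercised by an identical-clouds
symmetry test (p ≈ 0.5).

**Descriptive interspecific tests.** `species_effect_test()` reports a
maximum-likelihood likelihood-ratio test of the species factor per trait
and level. It is reported in the study output for orientation but is not an
inferential endpoint.

## The synthetic-data generator

The generator's purpose is a study-shaped dataset in which every downstream
quantity has known ground truth.

**Oscillator.** Activity series come from a noise-driven FitzHugh–Nagumo
relaxation oscillator,
$$dv = (v - v^3/3 - w + I)\,dt/\tau + \sigma\,dW, \qquad
  dw = \epsilon\,(v + a - b w)\,dt/\tau,$$
integrated by Euler–Maruyama at a 1 s step with stochastic forcing on the
activation variable only, a 1 h burn-in, 30 s sampling, and per-series
rescaling to [0, 1]. With the classic excitability parameters
($\epsilon = 0.08$, $a = 0.7$, $b = 0.8$, $I = 0.5$) the deterministic
system's limit cycle takes about 39.5 model time units (verified in the
tests against a fine-step ODE integration), so the time mapping
`tau_s = 60` (one model unit = one minute) produces a ~40 min ultradian
burst cycle. Two parameters act as the phenotype dials:

- `tau_s` rescales time and therefore the period, without changing the
  cycle shape;
- `noise_sd` (the stochastic forcing) controls rhythm regularity: stronger
  forcing makes burst timing irregular and lowers the coherence factor
  smoothly from ~7.4 toward ~3 with no pathological behavior anywhere in
  the usable range.

Stronger forcing also shortens the mean cycle (noise kicks the trajectory
over the excitation threshold early). Because the generator treats period
and rhythm strength as *independent* latent traits, it compensates: the
expected period at each noise level was measured from the generator itself
(30 realizations per knot, stored in an internal calibration table) and
`tau_s` is scaled so the realized dominant period matches the latent period
target regardless of the noise level. `fhn_params()` also offers an
additive observation-noise channel (`obs_noise_sd`, temporally correlated
at the minute scale) that emulates segmentation jitter; it is available for
robustness experiments but is not used by the study generator, whose
rhythm-strength dial is the process noise.

**Trait evolution.** `simulate_chronogram()` draws a pure-birth tree
rescaled to unit height. Terminal branches shorter than 4% of tree height
are rejected and the tree redrawn: a chronogram of described species has no
near-zero splits, and allowing them would let within-species sampling noise
dominate the rate estimate through the $C^{-1}$ weighting of close sister
pairs. Species-level log-period and log-rhythm-strength latents then evolve
by Brownian motion *along the tree* (`simulate_bm_traits()`), with rate
equal to the squared interspecific SD per unit height, so tip latents have
the configured marginal SDs, close relatives resemble each other, and the
downstream rate estimates target exactly the planted rates. Each colony and
individual receives an intraspecific log-normal jitter of its species'
latents; both recordings of a colony share the colony's values.

**Default study design** (`study_config()`): 22 species; 4 colonies per
species recorded twice for 1,740 frames (14.5 h at 30 s); 4 isolated
individuals per species recorded for 1,020 frames (8.5 h); interspecific
SDs (log scale) of 1.0 (colony) vs 0.333 (individual) for rhythm strength —
the 3:1 planted emergence signal — and 0.15 at both levels for period;
intraspecific SDs of 0.15 (rhythm) and 0.35 (period). Three of these
choices deserve their reasoning spelled out:

- *Equal per-species unit counts at the two levels* (4 colonies vs 4
  individuals). The rate estimate is inflated by within-species sampling
  noise in inverse proportion to the number of resampling units; unequal
  counts would build a level asymmetry into the null and bias the rate
  comparison for *every* trait, including ones with no planted difference.
- *Within-species period spread larger than between-species spread*
  (0.35 vs 0.15). Individual ants are far less repeatable than colony
  averages — the wide within-species boxplots typical of such data — and
  this regime keeps the bootstrap's dispersion commensurate with the
  across-study sampling variability of the rate estimates, which is what
  makes the period comparison well calibrated.
- *Rhythm-strength SDs on the log scale around process noise 0.3*, spanning
  noise ≈ 0.05–1.35 across species, i.e. coherence factors from ~7.4 down
  to ~3 — a spread comparable to real colony-level phenospaces — while
  staying inside the range where the period calibration table is monotone.

**What the generator does not emulate.** It is phenomenological: there is
no mechanistic ant-to-ant coupling (colony series are single oscillators,
not emergent sums of interacting workers), no diel or seasonal structure,
no missing data, no unequal species sampling, and image fixtures are
disc-shaped blobs rather than ant morphologies. Passing tests therefore
demonstrate that the *pipeline* recovers planted signals of realistic size
and calibrates correctly under a realistic null — they do not validate the
biological model of how real colonies generate rhythms.

## Tracking-stage choices

- **Adaptive threshold**: local-mean binarization with an integral-image
  box filter whose half-width is 1/16 of the ROI's shorter side (window ≈
  1/8), and an offset of $(1 - \text{sensitivity}) \times$ half the frame's
  intensity range. Using the range rather than an absolute offset makes the
  binarization invariant to global brightness shifts. Constant-intensity
  frames binarize to background with a warning.
- **Optical flow**: Horn–Schunck global-smoothness flow, 100 relaxation
  iterations, regularization weight `alpha = 2`. With truncated relaxation
  a small weight lets flow diffuse far into the textureless background and
  inflates the mean magnitude several-fold relative to the displaced pixel
  mass of the moving objects; `alpha = 2` keeps the field localized so the
  mean magnitude tracks displaced mass (the fixture tests assert this
  within 30%), while preserving monotonicity in object speed.
- **Centroid tracking**: midpoint-threshold foreground, largest connected
  component (`EBImage::bwlabel`), ties broken by the lowest (row, column)
  index; frames with no foreground are flagged and linearly interpolated,
  and more than 20% failures abort with an error.
- **Open field**: instantaneous speed is displacement × fps /
  body length; the mean is taken over frames exceeding 0.5 BL/s only. A
  track with no supra-threshold frame raises a dedicated "never-moving"
  error rather than returning 0, because a mean over an empty set is
  undefined, and silently returning 0 would fabricate a speed of an ant
  that never walked.

## Numerical choices and degenerate inputs

- Ultrametricity is checked to a relative tolerance of $10^{-6}$; trees
  are pruned to the species with data before fitting.
- `rescale_unit()` refuses constant series by name; the oscillator's own
  rescaling leaves numerically constant output (deterministic fixed point)
  shifted but unstretched rather than amplifying noise floors.
- The REML profile guards the degenerate zero-residual-variance case and
  the unidentifiable all-singleton design, both collapsing to species
  means.
- Integration failure in the oscillator (parameter blow-up) reports the
  step index; period-grid construction refuses records shorter than 64
  points or two octaves.
- All stochastic stages take explicit integer seeds; `run_study()` spawns
  per-stage child seeds from one master seed so stages can be rerun in
  isolation, and reports are byte-identical across reruns.

## Validation design and problem sizes

The test suite exercises the pipeline at sizes chosen to keep the full run
in minutes while leaving the statistical properties measurable; the two
headline experiments are:

- **Null calibration**: 200 synthetic studies with equal interspecific SDs
  at both levels and symmetric replication (12 species, 3 colonies × 1
  recording vs 3 individuals, 600-frame series), 200 bootstrap replicates
  each; the empirical rejection rate at p < 0.05 must stay near the nominal
  level (observed 0.035).
- **Dissociation**: 20 synthetic studies at the full default design
  (3:1 rhythm-strength SDs, equal period SDs), 500 bootstrap replicates;
  the study-level conclusion — rhythmicity rate difference significant,
  period difference not — must hold jointly in at least 16 of 20 seeds
  (observed 16).

## Known limitations

- The coherence factor saturates near ~7.5 for clean signals of this
  record length, compressing differences among highly rhythmic species.
- Dominant-period estimates for nearly arrhythmic series (β below ~3) are
  unstable by nature — the periodogram is almost flat — and this is real
  structure, not a bug: such series' period values carry little
  information, at either level of organization.
- The bootstrap rate test inherits the general limitation of
  resampling-within-species designs: its dispersion reflects within-species
  variability only, so with very high replication per species it can be
  anti-conservative relative to across-study variability.
- The optical-flow magnitude is aggregation-sensitive (regularization
  weight, iteration count); it is a relative activity measure, not a
  calibrated speed.
- PGLS assumes a strict Brownian correlation structure; no Pagel's-lambda
  or Ornstein–Uhlenbeck variants are provided.
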