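---
title: "Validating wearable heart-rate monitors with repeated-measures Bland-Altman analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable heart-rate monitors with repeated-measures Bland-Altman analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hragree)
library(dplyr)
```

## The problem

Consumer wearables (earbuds, watches, rings) estimate heart rate optically
(photoplethysmography), and their accuracy is usually judged against an
ECG-derived chest strap worn at the same time. A validation session yields
two time series per participant: a *criterion* stream (chest strap, dense
and regular, often derivable from R-R intervals) and an *index* stream (the
wearable, irregularly sampled). Because each participant contributes
hundreds of paired observations, the classical Bland-Altman recipe —
treat all pairs as independent, report bias ± 1.96 SD — understates
uncertainty and conflates two distinct sources of disagreement: stable
per-person offsets and epoch-to-epoch fluctuation.

`hragree` implements the repeated-measures variant end to end: stream
ingestion, artefact filtering, epoching, pairing, a variance-components
agreement model, cluster-bootstrap uncertainty, and error metrics
stratified by exercise intensity. A synthetic-data generator emulating a
graded treadmill protocol makes every stage testable without any device
export.

## From raw streams to paired epochs

1. **Ingestion** (`read_hr_csv()`, `read_rr_csv()`). Neutral CSV schemas;
   R-R intervals are converted beat-by-beat via `hr = 60000 / rr_ms`.
   Physiological plausibility bounds — heart rate in (25, 250) beats/min,
   R-R in (200, 3000) ms — are applied at read time with logged counts, so
   the artefact budget of a dataset is visible rather than silent.
2. **Spike filtering** (`remove_spike_artifacts()`). Chest-strap R-R
   streams occasionally contain transient detection noise. A sample is
   deleted when it jumps by at least 10 beats/min from its predecessor
   *and* the very next sample returns to the pre-spike level. "Returns" is
   operationalised as a one-sample look-ahead within `return_tolerance`
   (default 5 beats/min) of the pre-spike value: a single-parameter
   reading of "brief and isolated" that leaves genuine sustained steps
   (real cardiodynamics) untouched. Endpoints are never removed. With
   `return_tolerance <= jump_threshold` the filter is idempotent.
3. **Epoching** (`epoch_aggregate()`). Both streams are averaged over
   non-overlapping 5-s windows. Windows are half-open
   `[5k, 5k+5)` and anchored at *absolute* multiples of the epoch length
   (`floor(t/5)`), not at session start, so the two devices land on the
   same grid without any negotiation; a sample exactly on a boundary
   belongs to the later window.
4. **Pairing** (`pair_epochs()`). An epoch enters the analysis only if
   both devices contributed at least one sample to its window; this
   realises nearest-neighbour matching at the 5-s resolution while
   excluding one-sided windows. The difference is always
   `index - criterion`.

## The agreement model

Let $d_{it}$ be the paired difference for participant $i$ in epoch $t$:

$$d_{it} = \mu + b_i + e_{it}, \qquad b_i \sim N(0, \tau^2), \qquad
  e_{it} \sim N(0, \sigma^2),$$

with $e_{it}$ optionally AR(1)-correlated within participant
($\mathrm{cor}(e_{it}, e_{is}) = \phi^{|t-s|}$). $\mu$ is the systematic
device bias, $\tau^2$ the variance of stable per-person offsets, and
$\sigma^2$ the epoch-to-epoch measurement noise. The 95% limits of
agreement use the **total** variance,

$$\mathrm{LoA} = \mu \pm 1.96\,\sqrt{\tau^2 + \sigma^2},$$

i.e. the interval expected to contain 95% of single-epoch differences for
a new participant. The 1.96 multiplier is fixed; no small-sample
$t$-adjustment is applied.

### Estimation

`fit_agreement()` uses restricted maximum likelihood, written as a profile
over the variance ratio $\lambda = \tau^2/\sigma^2$ (and $\phi$ when
enabled): given $(\lambda, \phi)$, the GLS intercept and $\hat\sigma^2$
have closed forms, so the search is one- or two-dimensional. For the
per-participant covariance $\sigma^2 (R + \lambda \mathbf{1}\mathbf{1}')$
a Woodbury identity reduces everything to the quadratic forms
$\mathbf{1}'R^{-1}\mathbf{1}$, $\mathbf{1}'R^{-1}d$, $d'R^{-1}d$, which
for AR(1) are $O(n)$ via the tridiagonal inverse. With $\phi = 0$ the fit
needs only each participant's epoch count, sum, and sum of squares — which
is what makes the cluster bootstrap essentially free.

Numerical choices worth knowing:

* the ratio is optimised on the log scale over $\lambda \in
  [e^{-20}, e^{12}]$ with the boundary $\lambda = 0$ checked explicitly;
  $\hat\tau^2$ is truncated at zero and flagged (`tau2_truncated`) rather
  than allowed negative, matching standard variance-components practice;
* AR(1) starting values come from the independence fit and the lag-1
  autocorrelation of within-participant residuals, then Nelder-Mead on
  $(\log\lambda, \mathrm{atanh}\,\phi)$;
* if every difference is identical the fit short-circuits to a flagged
  degenerate result ($\mu$ = that value, $\tau^2 = \sigma^2 = 0$) instead
  of failing;
* the CI for $\mu$ is Wald (normal quantile) using the GLS standard error
  at the estimated ratio.

The test suite cross-checks the estimator against closed-form one-way
ANOVA estimators on balanced layouts, a dense grid search over the
restricted likelihood built from explicit covariance matrices, and the
independent implementations in `lme4` (independence) and `nlme` (AR(1)).

AR(1) is off by default: with 5-s epochs much of the serial dependence is
absorbed into the epoch means, and the limits of agreement depend on the
marginal variances only. The fitted object stores the restricted
log-likelihood so users can compare the two fits directly; enabling AR(1)
mainly matters for the standard error of $\mu$ when residual correlation
is strong.

### Uncertainty for the limits

The published quantity of interest is the pair of LoA bounds, whose
sampling distribution depends on both variance components.
`cluster_bootstrap_loa()` resamples *participants* with replacement
(B = 1000 by default, percentile intervals), refitting the model per
replicate; resampling whole clusters is the resampling scheme that
respects the dependence structure the model asserts. Replicates that draw
fewer than two distinct participants cannot identify $\tau^2$ and are
redrawn (counted and reported). A seed makes the intervals exactly
reproducible, and the RNG state of the caller is restored afterwards.

### Diagnostics

`proportional_bias_check()` regresses the difference on the pair mean
$(\text{index}+\text{criterion})/2$ with participant-clustered standard
errors (`sandwich::vcovCL`): a CI excluding zero indicates proportional
bias. The heteroscedasticity statistic is the slope of $|$residual$|$ on
the pair mean — positive when dispersion grows with heart rate, the
signature pattern of optical sensing during vigorous exercise.

## Intensity zones and error metrics

Zones use the criterion heart rate as a percentage of age-predicted
maximum ($\mathrm{HR}_{max} = 220 - \mathrm{age}$): rest $<40\%$, light
$[40, 60)\%$, moderate $[60, 75)\%$, vigorous $\geq 75\%$. Boundaries are
half-open on the percent scale so real-valued percentages such as 59.5 are
classifiable.

`error_summary()` reports MAE ($\mathrm{mean}\,|d|$), MAPE
($\mathrm{mean}\,100|d|/\mathrm{criterion}$), and the signed mean error
under two weightings, both of which appear in validation practice:
*participant-averaged* (metrics per participant first, then an unweighted
mean across participants, so a participant with a long recording does not
dominate) and *pooled* (flat mean over epochs). `zone_summary()` produces
the per-zone table (counts, device means, bias, SD of differences,
MAE/MAPE) and always records which weighting was used; the two coincide
exactly when participants contribute equal epoch counts.

## The synthetic study generator

`generate_study()` emulates the kind of laboratory session these
validations use, with all parameters in `sim_config()`:

* **Cohort**: 40 participants, ages $N(23.8, 3.6^2)$ truncated to 18-65.
* **Protocol**: rest (240 s), five stages targeting 40/55/65/75/85% of
  age-predicted HRmax (210 s each — the middle of the typical 3-4 min
  steady-state stage), 120-s recoveries between stages at rest+10
  beats/min, 300 s final recovery. At defaults this yields roughly 415
  paired epochs per participant, matching the scale of a 40-50 minute
  treadmill session.
* **Kinetics**: heart rate relaxes toward the current target
  exponentially with time constant 35 s — the simplest model with a
  realistic on/off-kinetics speed, and enough to exercise the pipeline
  during rapid transitions.
* **Criterion device**: 1 Hz sampling, independent N(0, 0.5²) jitter —
  chest straps track ECG closely, so their noise floor is small.
* **Index device**: irregular sampling (gaps uniform on 1-2 s, forcing
  the pairing logic to handle unequal densities), participant offset
  $b_i \sim N(0, \tau^2)$, bias $\mu$, and AR(1) noise ($\phi = 0.6$ per
  sample) whose SD scales with intensity as
  $1 + 0.02\,\max(0, \mathrm{HR} - \mathrm{HR}_{rest})$ — dispersion
  roughly doubling between rest and light exercise and continuing to grow
  with workload, the qualitative heteroscedasticity pattern optical
  sensors show.
* **Artefacts**: isolated ±15 beats/min spikes on the criterion stream at
  0.5/min (above the 10 beats/min filter threshold, separated by at least
  two clean samples so the filter's one-sample look-ahead can see
  baseline on both sides), and whole-epoch index dropouts with
  probability 0.02.

One calibration deserves emphasis. Averaging $\approx 3.3$ correlated
samples into a 5-s epoch shrinks noise variance by a computable factor
(`effective_epoch_factor()`, about 0.65 at defaults). The agreement model
— like the published analyses it mirrors — lives at the *epoch* level, so
`sim_config()` interprets `sigma2` as the epoch-level noise variance and
inflates sample-level noise by the inverse square root of that factor
(`calibrate_epoch_variance = TRUE`). Consequently, at defaults with
`hetero_slope = 0`, the SD of paired 5-s epoch differences is
$\sqrt{\tau^2 + \sigma^2}$ to within Monte-Carlo error, and parameter
recovery can be checked against the configured values directly. The
manifest written alongside the study records the shrink factor and the
effective epoch-level variance for the uncalibrated reading too. With
`hetero_slope > 0` (the default), `sigma2` is the noise floor at resting
heart rate and realised total dispersion is larger.

The generator is deliberately statistical, not biophysical: it contains
no PPG waveform, no motion-artefact spectrum, no skin-tone physics, and
its missingness is independent of workload, whereas real wearable
dropouts cluster at high intensity. Tests passing on synthetic data
therefore demonstrate that the *pipeline and estimators* behave correctly
under the assumed error structure — not that any particular device is
accurate.

## Problem sizes used in the shipped checks

The test suite fits the model on simulated studies of 40 participants ×
420 epochs (the scale of a typical published validation), runs 100-fold
parameter-recovery and bootstrap-coverage studies at that scale (B = 200
per replicate — percentile intervals stabilise well before B = 1000 for
coverage purposes), and verifies estimator equivalence on 50 small
balanced layouts against the ANOVA and grid-search oracles. These sizes
were chosen so the whole suite exercises study-scale behaviour while
remaining quick to run routinely.

## Worked example

```{r example, eval = FALSE}
dir <- file.path(tempdir(), "demo-study")
generate_study(sim_config(n_participants = 12, seed = 7), dir = dir)

res <- run_pipeline(
  index_csv = file.path(dir, "index_hr.csv"),
  criterion_csv = file.path(dir, "criterion_hr.csv"),
  participants_csv = file.path(dir, "participants.csv"),
  config = pipeline_config(n_bootstrap = 500, seed = 7)
)

res$fit           # bias, variance components, LoA with bootstrap CIs
tidy(res$fit)     # the same, tibble-shaped
res$zones         # per-intensity-zone agreement table
autoplot(res$fit) # Bland-Altman plot
```

## Known limitations

* No regression-based (heart-rate-dependent) limits of agreement: the
  diagnostics *detect* heteroscedasticity but the reported LoA assume a
  constant total SD, so they are conservative at rest and optimistic at
  vigorous intensity when dispersion grows with workload.
* Random intercepts only — no random slopes, no participant-specific
  proportional bias.
* Percentile bootstrap intervals, not BCa or exact small-sample (MOVER)
  intervals; with very few participants (< ~10 clusters) they can
  undercover.
* Pairing is shared-window membership at the epoch resolution; no
  sub-epoch lag estimation (cross-correlation or DTW) and no
  interpolation of missing epochs.
* The age-based HRmax formula (220 − age) carries well-known individual
  error; zone boundaries inherit it.
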