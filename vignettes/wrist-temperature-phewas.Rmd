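---
title: "Wrist-temperature rhythms and phenome-wide disease risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-temperature rhythms and phenome-wide disease risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscan)
```

This vignette is the package's own account of what it computes and why:
the statistical model, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open. No empirical claim is made here
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. From sensor units to rhythm amplitude

Wrist-worn actigraphy devices report temperature in arbitrary sensor
units $X$; the calibrated Celsius value is the fixed linear map
$T = (500X - 2550)/256$, inverted exactly by
`convert_celsius_to_raw()`. Epochs flagged as non-wear are
non-physiological and become missing values — never fill values — before
any fitting (`mask_nonwear()`).

The diurnal rhythm of each participant is summarized by a
single-component cosinor: ordinary least squares of temperature on
$\{1, \cos(2\pi t/24), \sin(2\pi t/24)\}$ over wear epochs. Writing the
fit as $M + a\cos\omega t + b\sin\omega t$, the **mesor** is $M$, the
**amplitude** $A = \sqrt{a^2+b^2}$ (mesor-to-peak; peak-to-trough is
$2A$) and the **acrophase** $\phi = \operatorname{atan2}(b,a)/\omega$,
reported as the clock time of the fitted peak in $[0,24)$. Because the
basis is linear, missing epochs are simply omitted; a design that does
not span the period (all epochs at one time of day) is rank-deficient and
the participant is flagged rather than fit.

Assumptions worth stating: the cosinor captures only the fundamental
24-h component. Real wrist-temperature traces have a flat nocturnal
plateau and an afternoon shoulder; those harmonics are orthogonal to the
fundamental over whole days, so they inflate the residual, not the
amplitude estimate. Under iid noise with SD $\sigma$ the amplitude
standard error is approximately $\sigma\sqrt{2/n}$, the benchmark the
tests use.

**Quality control.** Amplitudes above 10 °C are non-physiological and
dropped; the boundary is a strict inequality (exactly 10 °C is kept),
a documented convention for an edge that essentially never occurs.
The minimum-data rule — at least 72 h of wear epochs spanning at least 3
distinct days, both configurable — stands in for the upstream pipeline's
unpublished "insufficient data" criterion.

## 2. Amplitude corrections

Two measurement artifacts are corrected before any survival modelling.

**Device-cluster bias.** Device IDs fall into batches (A: id < 7500, B:
7500–12499, C: 12500–19999, D: ≥ 20000, half-open on the left) with
multiplicatively shifted readings. Each record's amplitude is scaled by
(pooled median)/(cluster median), so every cluster's median equals the
original pooled median exactly and within-cluster ranks are untouched.

**Season.** Skin-temperature amplitude is seasonally modulated. A
cosinor over day-of-year $d$ (period 365.25 d, origin January 1) is fit
to $\log A$ and the corrected amplitude is $\exp(\mu + r_i)$ with $r_i$
the residual. The seasonal basis is centred before fitting, which makes
the correction preserve the cohort geometric mean exactly rather than
only approximately for unevenly distributed measurement dates.

**Order.** Device correction runs first by default: clusters are
associated with season of measurement, and equalizing medians first
prevents the seasonal fit from absorbing device bias. The order is
configurable (`correct_amplitudes(order = "season_first")`) and the swap
is covered by a test; on bias-free data both orders are near-identity.
The seasonal fit uses the whole analysis cohort by default (a
repeat-measurement sub-cohort could be used instead by passing only those
records).

**Calibration diagnostic.** `device_calibration_check()` compares the
variance of per-device means against a null built by permuting device
IDs across participants, $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(n_{\text{perm}}+1)$. Mean temperature typically shows
strong device bias; cosinor amplitude, being a within-participant
contrast, is far more robust — which is the empirical justification for
analyzing amplitudes rather than levels.

## 3. Landmark phenotype cohorts

Diagnoses enter as ICD-10 codes and are grouped into PheCODE phenotypes
by dot-insensitive longest-prefix matching. Each phenotype carries
*exclusion phenotypes*: related conditions whose history marks a likely
undiagnosed case. A small synthetic toy map (19 ICD-10 prefixes, 16
phenotypes, labelled by common usage) is bundled for testing; a full map
in the same two-file schema is accepted.

The time-to-event design guards against reverse causation: subjects with
the phenotype or any exclusion phenotype — hospital or self-reported —
dated on or before actigraphy + 1 year are excluded from that
phenotype's analysis entirely (but not from other phenotypes). Everyone
else enters the risk set at the landmark, implemented as delayed entry at
$t = 1$ year on the "years since actigraphy" timescale rather than by
shifting the clock; this keeps event times interpretable and makes the
left truncation explicit to the Cox fitter. The event is the first
hospital diagnosis after the landmark; censoring is at death or the
administrative end of follow-up. Subjects whose follow-up ends inside
the lag contribute no risk time and are dropped with a recorded count.

Phenotypes with fewer than 200 cases are excluded
(`case_count_filter()`), a threshold motivated by the power analysis in
section 5.

## 4. The phenome-wide Cox scan

Each retained phenotype gets a Cox proportional-hazards model with the
corrected amplitude (°C) as the exposure and covariates for sex,
ethnicity, smoking, age band (40–55/55–60/60–65/65–70/70–80), BMI,
college education, Townsend index, alcohol frequency and self-rated
health; complete-case rows only; Efron tie handling (diagnosis dates are
day-resolution, so ties are certain); and a subject-level robust
sandwich variance (`coxph(..., id = participant_id)`; no additional
clustering, since there is one row per subject). The reported p-value is
the two-sided Wald test on the amplitude coefficient with the robust SE.

Effects are reported in the decrease framing: HR per 1 °C lower
amplitude is $e^{-\beta}$ and per 2 population SD — the fixed constant
1.8 °C, not re-estimated per run — is $e^{-1.8\beta} =
(e^{-\beta})^{1.8}$, with CI endpoints transformed identically. Across
phenotypes, Benjamini–Hochberg q-values control the FDR and a Bonferroni
flag marks $p < \alpha/m$; non-converged or separated fits are excluded
from the family with $m$ reduced accordingly and the exclusion recorded.

Further models follow the same contract: exposure-by-sex and
exposure-by-age-band interactions tested by a robust Wald chi-square on
the interaction block (phenotypes with an event-free stratum are skipped
with a reason); an all-cause mortality model with no phenotype
exclusions, refit separately under/over age 65 (an exact partition of
the risk set); and device-cluster sub-cohort validation (cluster A
versus B + C) with sign-agreement and CI-overlap concordance summaries.

**Diagnostics.** `schoenfeld_check()` regresses scaled Schoenfeld
residuals on event time (identity transform) per term. Violators at
$p < 0.01$ trigger a documented refit — a linear time-interaction
`tt(x) = x·t` for quantitative terms, stratification for categorical
ones — and the exposure HR of the refit is compared to the original as a
relative change. Penalized-spline linearity checks and competing-risks
refits are deliberate non-goals.

## 5. Power by simulation

`power_by_simulation()` motivates the 200-case threshold. Each
replicate draws a standard-normal exposure $z$ for $n$ subjects,
exponential event times with rate $\lambda e^{\beta z}$ and
administrative censoring at unit time, with $\lambda$ calibrated by
numerically solving $n\,E_z[1 - e^{-\lambda e^{\beta z}}] =$ target
events (adaptive quadrature + root finding, so the mean event count hits
the target without simulation tuning). Power is the fraction of
replicates with two-sided Wald $p < \alpha$. For $\beta = 0.2$ per SD
and 200 events the analytic approximation
$\Phi(\sqrt{d}\,|\beta| - z_{1-\alpha/2}) \approx 81\%$, and the
simulation agrees; at $\beta = 0$ the "power" collapses to the test size
$\alpha$, which the tests use as a size check.

## 6. What the synthetic cohort emulates

The generator exists so that every downstream stage has known ground
truth. Its defaults describe one fixed set of study conditions:

| parameter | default | rationale |
|---|---|---|
| days, epoch | 7 d, 5 min | week-long wear; epoch length is configurable because device epochs vary (tests use 30–60 min for speed; the cosinor is insensitive to epoch length at these scales) |
| mean amplitude | 2.5 °C | typical distal-skin diurnal swing (≈5 °C peak-to-trough) |
| amplitude SD | 0.9 °C | so 2 SD = 1.8 °C, the reporting scale |
| amplitude prior | log-normal | amplitudes are positive; season acts multiplicatively on log A; `sd_log_amplitude` solved in closed form from mean/SD |
| mesor | N(31, 0.8) °C | distal skin temperature level |
| noise | AR(1), SD 0.5 °C, φ = 0.5 | epoch noise is serially correlated (environment, posture) |
| waveform | fundamental + 2nd harmonic (ratio 0.25) | flattens the nocturnal peak into a plateau; the shape's fundamental Fourier component is exactly the unit cosine, so the cosinor recovers the ground-truth amplitude with zero shape bias |
| acrophase | 4 h ± N(0, 1.5 h) | nocturnal peak with chronotype phase spread |
| non-wear | 5%, contiguous blocks (mean 2 h), reads ≈26 °C | realistic masking; off-wrist readings drift toward ambient |
| seasonal modulation | exp(0.1·cos(2πd/365.25)) | mild winter/summer amplitude cycle |
| device clusters | A/B/C at 65/20/15%, biases 1.00/1.05/0.95 | batch bias to exercise the median equalization (cluster D is reserved for repeat measurements and absent by default) |
| study window | Jun 2013 – Dec 2015, admin end Sep 2021 | gives ≈4.75–7.25 y (mean ≈6 y) of post-landmark follow-up |
| assessment gap | N(5.7, 1.2) y, clipped to 2.8–8.7 | covariates predate actigraphy |

Disease processes are exponential proportional-hazards models: the rate
for disease $k$ is $\text{baseline}_k \cdot \exp(\beta_k (A_i -
\bar A))$, where $A_i$ is the participant's **bias-free** amplitude.
This is a deliberate structural choice: the seasonal factor and device
bias enter only the *measured* series, so the correction chain is
causally the right thing to do and its success is measurable as recovery
of $\beta_k$. Baseline rates are per person-year at the mean amplitude.
Configurable fractions of subjects receive pre-actigraphy diagnoses and
within-lag diagnoses to exercise the exclusion rules, and hospital
diagnoses after death are suppressed.

What the generator does **not** emulate: accelerometry and the upstream
non-wear detection (wear flags are an input), daylight-savings
transitions, covariate-dependent disease risk beyond amplitude (available
but zero by default), non-exponential baseline hazards,
informative censoring, diagnosis-coding noise, and within-week amplitude
drift. Passing tests therefore demonstrate the *pipeline's* correctness
and calibration under a realistic generative model — not that real
wrist-temperature data satisfy the proportional-hazards or cosinor
assumptions.

## 7. Numerical choices and degenerate inputs

* Cosinor solved by QR; rank < 3 is a fit error, flagged per participant.
* Daily-median normalization uses midpoint interpolation for even
  counts; empty days are omitted.
* Permutation p-values use the add-one estimator, never exactly zero.
* Cluster correction with a zero cluster median is a data error
  (impossible after QC, which requires positive amplitudes).
* `hr_scaling` re-sorts transformed CI limits so lower ≤ upper for either
  sign of $\beta$.
* Event times are inverse-CDF transforms of uniforms
  ($-\log u/\lambda$), checked in the tests against `qexp`.
* All generator stages derive their seeds from the single `seed` via a
  fixed integer map, so one integer reproduces every table exactly.
* Quantile strata with zero person-time are merged into their neighbor
  with a message; the trend test is a Poisson log-linear model on the
  stratum index with a person-time offset.

## 8. Problem sizes used in the test suite

The suite is sized for a single CPU: the end-to-end recovery experiment
runs 100 seeded replicates of the full chain (generator → preprocessing
→ cosinor → corrections → landmark cohort → Cox) at $n = 5000$
participants with hourly epochs and a true $\beta = -0.3$ per °C
(≈750 events per replicate), checking recovery within two robust SEs in
at least 93 of 100 runs. Null-calibration checks (permutation p-values,
global-null scan, interaction nulls, stratum trend nulls) use 25–500
replicates at $n$ = 250–2000 with KS tests at $\alpha = 0.01$. The
correction near-identity checks use $n$ = 3000–15000 records because the
corrections' own estimation noise scales as $1/\sqrt{n}$ and the stated
tolerances (0.999 correlation; <1% median relative change) are
properties of cohort-scale samples. The acceptance script simulates
4000 replicate cohorts of $n = 1000$ for the power computation.

## 9. Known limitations

* Single-component cosinor only; multi-harmonic and shape-based
  (functional) rhythm descriptors are out of scope.
* The PheCODE map bundled is a synthetic toy; real analyses must supply
  the full map in the same schema.
* ICD-9, competing-risks refits, penalized-spline dose-response and any
  genetic analyses are non-goals.
* The robust variance assumes one row per subject; recurrent-event or
  clustered designs would need an explicit cluster column.
* Calendar-date arithmetic uses 365.25-day years; day-level rounding of
  simulated event dates introduces ≤1-day discretization, negligible on
  a years timescale.
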