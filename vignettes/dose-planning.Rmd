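---
title: "Individualised activity planning for CZT ERNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualised activity planning for CZT ERNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernadose)
```

## The clinical problem

Equilibrium radionuclide angiography (ERNA) quantifies left-ventricular
ejection fraction in patients monitored for chemotherapy cardiotoxicity. On
high-sensitivity CZT SPECT cameras, a fixed 550 MBq dose of Tc-99m-labelled
human serum albumin produces far more counts than the analysis needs, so the
administered activity can be tailored to each patient: choose a *target
acquisition count rate* `CR_T` (kcps) that still yields reproducible LVEF
analyses, predict the count rate each patient would produce at the reference
activity from their anthropometrics, and scale the activity so the predicted
rate lands on the target. `ernadose` implements that planning algorithm and a
synthetic-cohort harness for auditing it.

## The dosing model

Both dosing formulas start from a log-linear regression of the acquisition
count rate at the 550 MBq reference activity on weight $X_W$ (kg), height
$X_H$ (cm), coded sex $X_G$, and age $X_A$ (years):

$$\widehat{CR}_{550} = \exp\!\big(b_0 + b_W X_W + b_{W^2} X_W^2 + b_H X_H + b_G X_G + b_A X_A\big).$$

Two fitted coefficient sets are shipped (`eq1_coefficients()` with the
quadratic weight term, `eq2_coefficients()` without), and each implies a
dosing rule:

* **Fixed-offset rule** (quadratic variant): near the reference activity
  the count rate changes by a constant $k = 0.00756$ kcps per MBq, so
  $D = 550 - (\widehat{CR}_{550} - CR_T)/k$. Accurate for heavier patients
  but can suggest negative activities for the lightest ones.
* **Proportional rule**: count rate scales with activity, so
  $D = 550 \cdot CR_T / \widehat{CR}_{550}$. Always positive, but grows
  steeply for heavy patients.

`plan_dose()` combines them by a body-weight branch: the fixed-offset rule
at and above `weight_threshold_kg` (default 73 kg; the protocol was later
revised to 82 kg, available via configuration), the proportional rule below.
Planned activities are raised to a minimum-dose floor keyed on the target
rate — 150 MBq at 1.5 kcps and above, 100 MBq below, following paediatric
minimum-activity recommendations with a safety margin — and optionally
capped. Finally the activity is corrected for the signed delay between
scheduled and actual injection, rounded to the nearest 5 min (half away from
zero; the tie rule is a package choice, since only the 5-min granularity is
prescribed), using the Tc-99m physical half-life of 360.4 min:
$D \cdot 2^{-\Delta t / T_{1/2}}$.

Each branch is algebraically invertible, so
`predicted_count_rate_at_dose()` recovers the target exactly whenever no
floor or cap fired — a machine-precision invariant the test suite asserts —
and predicts the off-target rate when one did.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `target_count_rate_kcps` | — | desired acquisition rate (kcps); 1.7 balances dose against analysis reproducibility |
| `weight_threshold_kg` | 73 | branch cutoff, inclusive; 82 after the protocol revision |
| `slope_constant_kcps_per_MBq` | 0.00756 | count-rate change per MBq for the offset rule |
| `floor_policy` | 150 MBq ≥ 1.5 kcps, else 100 | minimum administered activity |
| `sex_coding` | male = 1, female = 0 | code entering the regressions |
| `half_life_min` | 360.4 | Tc-99m physical half-life |
| `effective_dose_coef_mSv_per_MBq` | 0.0062 | activity → effective dose |

**Sex coding.** The regressions only specify a 0/1 sex covariate, not which
sex is 1. The package default (male = 1) is the coding under which doses
planned for the predominantly female published groups reproduce the reported
group means; it is configurable because local refits may code differently.

**Effective-dose coefficient.** 0.0062 mSv/MBq is a reverse-engineered
default chosen so that typical individualised activities (~258 MBq) map to
~1.6 mSv; it is not an ICRP citation and should be overridden with the
locally mandated coefficient for formal dosimetry.

**No cap by default.** The offset rule can exceed 550 MBq for heavy
patients at high targets. Whether clinics cap there is protocol-dependent,
so the cap ships disabled; any plan above the reference activity is logged.

**Dose precision.** Planned activities are emitted at full precision;
`dose_rounding_MBq` provides an optional dispensing granularity (floors are
never rounded down through).

## The synthetic cohort generator

`cohort_preset()` packages one generator per published target-count-rate
group (1.0, 1.5, 1.7, 2.0, 2.7 kcps, and the standard-dose group), carrying
the group's size, female fraction, and the mean/SD of age, height, and
weight. `generate_cohort()` draws sex as Bernoulli and each anthropometric
independently from a normal distribution truncated to the plausibility
bounds (30–250 kg, 120–220 cm, 15–110 y), deterministically under a seed.
The 2.7 kcps preset forces the fixed-offset branch for every patient
(threshold 0), matching the earliest study period in which that equation
was used alone; the standard-dose preset plans everyone at 550 MBq, with
the predicted rate taken from the weight-branch regression since its
anthropometrics are on record.

**What the generator does not emulate.** Only marginal moments are
published, so the generator treats age, height, weight, and sex as
independent. Real cohorts correlate them (heavier patients are taller and
more often male), which *shrinks* the variance of the linear index feeding
the exponential. Because the dose is a convex function of that index on both
branches, the independent-marginals cohorts overestimate the published group
mean doses by roughly 5–10% and trigger the minimum-dose floors more often
than the clinic did (e.g. a nonzero floored fraction at 1.7 kcps, where the
clinic recorded none). Passing cohort-level checks therefore demonstrates
that the planning arithmetic and harness are correct to within the
acknowledged fidelity of the generator — not that the generator reproduces
the clinic's joint anthropometric distribution. A sex-conditional offset
hook was considered and left out of the defaults: with no sex-stratified
moments published, any values would be invented.

**Measurement noise.** Measured count rates are simulated as
`predicted * exp(eps)`, `eps ~ N(0, sigma_log^2)` — multiplicative because
count rates are positive and residual structure is unpublished.
`calibrate_noise_sigma()` chooses `sigma_log` so the large-sample $R^2$ of
the straight line fit of measured on predicted equals a target (0.80 by
default, the agreement reported for the clinical cohort); the expected
$R^2$ is strictly decreasing in sigma, and the root is found by bisection
to 1e-8 (the closed-form inversion of the same expression serves as an
independent oracle in the tests). Calibration needs between-patient
variance in the predicted rates, which a single fixed-target group barely
has — so it is performed on the six-group mixed study (n = 1650). A rare
paravenous-injection channel (probability 10/1650, the observed clinical
frequency) attenuates affected acquisitions by a configurable factor
(default 0.5 — a model choice; no attenuation magnitude is published).
`flag_paravenous()` flags acquisitions whose measured/predicted ratio falls
strictly below 0.5, a threshold at which calibrated ordinary noise
false-flags well under 1% of acquisitions.

## Audit statistics

`linear_fit()` (OLS slope/intercept, squared Pearson correlation) checks
measured-vs-predicted agreement; `summarize_doses()` reports per-group mean,
sample SD (n−1), and SEE = SD/√n of the planned activity plus floor usage;
`cohort_flow()` enforces the referral-flow conservation identity
`individualized = referred − exclusions − standard`; `mean_count_rate()`
averages the three on-screen readings; `lvef_agreement()` applies the
two-analyst rule — a difference of *exactly* 2 percentage points still
counts as sufficient, because "more than 2" is read strictly and no
pre-rounding is applied (whether clinics compare rounded integer LVEFs is
unspecified; supplying rounded values reproduces that behaviour). The ~5%
reanalysis frequency reported for the 1.7 kcps group depends on human
inter-analyst variability, which the package deliberately does not model;
it is a reference value only.

## Numerical and degenerate-input choices

* Validation rejects out-of-bound anthropometrics rather than clamping;
  rows missing height or weight fall back to the standard 550 MBq plan
  (`equation_used = "standard"`), mirroring the clinical fallback.
* Raw equation doses are returned unmodified — negative fixed-offset
  suggestions are legal intermediates; only `plan_dose()` guarantees the
  floor.
* The weight threshold is inclusive (73.0 kg doses by the fixed-offset
  rule).
* Single-plan summaries report SD 0 with a `degenerate` flag; a floor
  policy that does not cover the configured target, exhausted truncation
  bounds, and zero-variance calibration inputs all raise errors.
* Timestamps are ISO-8601, UTC, "." decimal separator, no locale handling.

## Problem sizes

The test suite and the reproduction script work at the study's own scale:
per-group cohorts of 250–432 patients, the mixed study of 1650, 20-seed
averages for cohort-level means, 10^4 randomised patients for the
formula-equivalence property, and 10^5 draws for Monte-Carlo checks of the
noise calibration. The full suite runs in a few seconds.

## Known limitations

* Independent anthropometric marginals (see above) — the dominant fidelity
  limit for cohort-level dose statistics.
* The regression coefficients are taken as printed constants; refitting
  them to local data is out of scope.
* No image processing, LVEF computation, DICOM/HL7 handling, or dispensing
  inventory management.
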