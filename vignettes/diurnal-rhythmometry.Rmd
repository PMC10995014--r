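---
title: "Diurnal cosinor rhythmometry of ambulatory HR and HRV: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diurnal cosinor rhythmometry of ambulatory HR and HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosinorHRV)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the design choices made where the design was genuinely open.

## 1. The problem

Ambulatory chest-belt ECG yields multi-day beat-to-beat interval (IBI)
records. Two cardiac autonomic summaries are of interest per 5-minute
segment: mean heart rate (HR, bpm) and the root mean square of
successive IBI differences (RMSSD, ms), a time-domain index of vagal
(parasympathetic) cardiac control. Both follow an approximately 24-hour
pattern — HR falls and RMSSD rises at night — and the question is
whether the *parameters* of that pattern (level, swing, timing) differ
between a clinical group and controls, and how they relate to
dimensional covariates.

## 2. Subject-level model

`cosinor_fit()` fits, by unweighted ordinary least squares,

$$Y(t) = M + \beta\cos(\omega t) + \gamma\sin(\omega t) + e(t),
\qquad \omega = 2\pi/\tau,\ \tau = 24\,\mathrm{h},$$

equivalently $Y(t) = M + A\cos(\omega t - \varphi)$ with
$A = \sqrt{\beta^2+\gamma^2}$ and $\varphi = \operatorname{atan2}(\gamma,\beta)$
wrapped to $[0, 2\pi)$. Assumptions: a single fixed-period harmonic is an
adequate mean model over the recording; residuals are uncorrelated
enough across 5-minute segments for OLS inference to be a reasonable
approximation. The least-squares formulation tolerates missing and
irregularly spaced segments, which is why it is the standard tool for
gappy ambulatory data.

Conventions, chosen once and used everywhere:

* **Acrophase reference and sign.** Times are hours since local
  midnight, so $\varphi \cdot \tau/(2\pi)$ is the clock hour of the
  fitted peak. We report positive lags in $[0, 2\pi)$; the classic
  cosinor literature reports the same angle negated, and
  `acrophase_convention()` converts between the two. Absolute clock
  mapping of a printed acrophase depends on this reference choice, so
  *differences* between groups (which are reference-free) are the
  quantity we test; `acrophase_diff_hours()` always takes the minimal
  signed arc.
* **Pooling days.** The main analysis pools both recording days into one
  fit per subject (the period is fixed at 24 h, so day two simply
  continues the phase). A per-day sensitivity restriction is available
  via `pipeline_config(days = )`.
* **Segment timestamp** is the window midpoint.
* **Identifiability guard.** A fit fails (condition class
  `cosinor_fit_error`) when fewer than 4 usable points remain, when the
  design is rank-deficient (e.g. all times equal modulo the period), or
  when the observations span less than a quarter period. Half a period
  or more is recommended for stable estimates; the hard guard is set
  lower so that 12-hour demonstration recordings remain fittable, and
  rank deficiency remains the decisive criterion.

Rhythm detection per fit is the zero-amplitude F test
$F = \frac{(TSS-RSS)/2}{RSS/(n-3)}$ on $(2, n-3)$ df; constant data
report $F = 0$, a perfect cosine reports $F = \infty$ with $p = 0$.

## 3. Group level: population-mean cosinor

`population_cosinor()` averages individual coefficient vectors
$(M_i, \beta_i, \gamma_i)$ over $k \ge 3$ subjects. The population MESOR
is exactly the mean of the individual MESORs; the population amplitude
and acrophase derive from $(\bar\beta, \bar\gamma)$. Uncertainty comes
from the *among-subject* dispersion of the coefficients (Bingham-type
variance components $c_{22}, c_{23}, c_{33}$): the amplitude CI is
$\hat A \pm t_{1-\alpha/2,\,k-1}\sqrt{c_{22}}$, and the acrophase CI
uses the classical arctangent construction. When the amplitude interval
reaches zero, the joint confidence region contains the origin and the
acrophase CI is reported as undefined — published group acrophase CIs
can look paradoxical in that regime, which is why we do not force them.
The group rhythm test is the Hotelling-type F on
$(\bar\beta, \bar\gamma)$ with $(2, k-2)$ df.

`compare_rhythms()` tests each parameter between two groups on
$(1, k_1+k_2-2)$ df: the MESOR test is the exact one-way ANOVA on
individual MESORs; the acrophase and amplitude tests are Wald-type F
statistics using the Bingham variance components
($\operatorname{var}(\hat\varphi) \approx c_{33}/A^2$,
$\operatorname{var}(\hat A) \approx c_{22}$). When the acrophase test is
significant at $\alpha$, the rhythm-parameter amplitude comparison is
unreliable (the parameter tests assume aligned phases), so the package
switches to a pooled-variance unpaired t test on the individual
amplitudes — two-sided by default and configurable, since published
analyses are not always explicit about sidedness. Hedges' g
($J = 1 - 3/(4\,df-1)$ times pooled-SD Cohen's d, large-sample CI)
accompanies the MESOR and amplitude contrasts.

## 4. Preprocessing

`preprocess_config()` defaults, with rationale:

| parameter | default | meaning |
|---|---|---|
| `hr_min`, `hr_max` | 30, 200 bpm | a beat whose instantaneous HR `60000/IBI` lies *strictly* outside the open interval is rejected; values exactly at a bound are retained |
| `detrend_lambda` | 500 | smoothness-priors regularization |
| `segment_length` | 300 s | 5-minute segments, at most 288 per 24-h day |
| `min_consecutive` | 30 s | shortest usable consecutive run per segment |
| `ectopic_threshold` | 0.20 | relative deviation from the local median that marks a beat ectopic |
| `max_corrected_fraction` | 0.05 | window-level rejection trigger |

Choices that were genuinely open, and how they were decided:

* **Automated ectopy correction.** Manual R-peak correction in a
  graphical tool is irreproducible; the package replaces it with a
  running-median rule: a beat deviating more than 20% from the median of
  its centred 11-beat neighbourhood is flagged and replaced by a natural
  cubic-spline interpolation through the unflagged beats. If more than
  5% of a 5-minute window needed correction, the whole window is
  rejected — heavy local ectopy means the segment cannot be trusted.
  These thresholds follow common HRV practice and are exposed in the
  config. The running median includes the centre beat; with at most a
  couple of outliers per window this equals the 10-neighbour median and
  costs O(n).
* **"30 s of consecutive IBI data"** is interpreted literally as the
  longest unbroken run of non-rejected beats within the window, not the
  total coverage: two 20-s runs split by an artifact do not qualify.
* **Segment alignment.** Segments count from the recording start (the
  protocol starts Saturday 10:00), not from a wall-clock grid; clock
  midpoints are derived from the start timestamp modulo 24 h.
* **Detrending order.** Smoothness-priors detrending is applied *per
  segment, before RMSSD only* — the Kubios convention. Mean HR uses raw
  intervals (detrending would remove the level information HR needs).
  Whether the original toolchain detrended before or after segmentation
  is not documented; the per-segment choice keeps segments independent
  and is flagged here as a package decision.
* **Mean HR convention.** `mean_hr()` averages instantaneous per-beat
  rates `60000/IBI` (Kubios "Mean HR"), with `per_beat = FALSE`
  switching to `60000/mean(IBI)`.

The smoothness-priors smoother removes the trend
$(I + \lambda^2 D_2^\top D_2)^{-1} z$ ($D_2$ = second-difference
operator) and returns the residual. Constants and straight lines lie in
the null space of $D_2$ and are removed exactly (tests assert
$<10^{-9}$); the implementation solves the banded sparse system with a
Cholesky factorization and matches a dense-matrix evaluation of the
closed form to $10^{-8}$.

## 5. The synthetic cohort generator

`simulate_ibi()` inverts the cumulative beat-count function of the
instantaneous rate $\mathrm{HR}(t) = M + A\cos(\omega t - \varphi)$ (a
closed-form integral) to place base beats, then perturbs each interval
with independent Gaussian noise of SD
$\sigma(t) = \mathrm{RMSSD}_{\mathrm{target}}(t)/\sqrt{2}$, so the
expected RMSSD of the clean series equals the target exactly — iid
perturbations were chosen over an AR process precisely because they make
this calibration analytic and testable (the suite checks a regression
slope of empirical on target RMSSD within [0.9, 1.1] over 10–100 ms).
Ectopy is injected as a premature beat at 0.6× the local interval plus a
compensatory pause restoring cumulative time — the standard ectopy
morphology, which exercises the correction rule. Non-wear windows delete
beats; the gap is absorbed into the next interval so that file
round-trips preserve absolute time and the plausibility filter
re-creates the gap downstream.

**Preset calibration.** The two cohort presets place group-mean cosinor
parameters at the values of a published two-group adolescent study
(HR MESOR 85.98 vs 79.44 bpm, amplitudes 12.42 vs 12.30 bpm, acrophases
1.81 vs 1.56 rad; RMSSD MESOR 44.82 vs 55.79 ms, amplitudes 13.90 vs
14.45 ms, acrophases 5.02 vs 4.73 rad; k = 29 vs 30), and covariate
distributions at the corresponding descriptive statistics (e.g. age
15.10 ± 1.06 vs 14.77 ± 1.52 years). Individual-level dispersions are
*not* published quantities, so the between-subject SDs are package
choices, made once and documented here: 8 bpm (HR MESOR), 4 bpm (HR
amplitude), 0.45 rad (acrophases), 15 ms (RMSSD MESOR), 6 ms (RMSSD
amplitude). They were chosen a priori as physiologically plausible for
ambulatory adolescent data and such that the analytic power of the
two-group MESOR contrast at the preset means ($d = 6.54/8 \approx 0.82$,
$n = 29/30$) is ≈ 0.87 — a well-powered but not degenerate design.
Back-solving SDs from the published population CIs instead would give
≈ 11 and 9 bpm and a substantially underpowered design; those CIs mix
trait variance with estimation error and asymmetric interval
constructions, so they were not treated as dispersion ground truth.
Clinical severity scores are generated as group-shifted normals — they
are labels for the association layer, not physiological drivers of the
simulated heart rate.

**What the generator does not emulate:** real circadian waveforms are
not pure cosines (evening plateaus, sleep-stage structure); HRV noise is
not white within segments; physical activity does not drive HR; and
covariates are independent of the cardiac signal given the group. Tests
passing on this generator therefore validate the *estimation machinery*
(recovery, calibration, error rates, bookkeeping), not the physiological
adequacy of a cosine model for any particular dataset.

## 6. Numerical choices and degenerate inputs

* Cosinor fits solve the 3-column QR directly; tests require agreement
  with explicit normal equations to $10^{-8}$ on 200 random instances.
* Constant outcomes: amplitude 0, rhythm F defined as 0.
* Zero among-subject dispersion: population CIs collapse to points
  rather than NaN; zero pooled SD makes Hedges' g undefined (NA).
* Acrophases are always wrapped; differences take the minimal signed
  arc, so a 23.9-vs-0.1-h comparison yields 0.2 h, not 23.8 h.
* Beat-level noise could in principle produce non-positive intervals;
  intervals are floored at 1 ms and the plausibility filter removes such
  beats downstream.
* Exclusion rule in the pipeline: a subject's outcome is dropped when
  the fit fails or fewer than 48 valid segments remain; exclusions are
  counted in the run manifest.

## 7. Problem sizes used in the validation suite

The test suite exercises full 48-h recordings for single subjects and
12–24-h recordings for multi-subject pipeline runs; Monte-Carlo error
rates use 1,000 replicates (type-I error of the zero-amplitude and
MESOR-comparison tests, bounds [0.03, 0.07] at α = 0.05), coverage of
the population MESOR CI uses 100 seeded replicates of 10-subject
cohorts, and the two-group power check uses 50 replicates at the preset
group sizes (29/30). These sizes give binomially tight checks while
keeping the suite comfortably fast on a single CPU.

## 8. Known limitations

* Single-harmonic cosinor cannot represent asymmetric diurnal profiles;
  multi-component extensions are out of scope.
* OLS inference ignores residual autocorrelation across segments; group
  comparisons inherit the usual equal-variance approximations.
* Acrophase enters the regression layer as a linear variable (matching
  the published analysis convention); this is only sensible when the
  group's acrophases are far from the wrap point. A circular-safe
  alternative is to regress on the $(\sin\varphi, \cos\varphi)$ pair.
* No multiple-testing correction is applied by default (the analyses
  are exploratory); `adjust_pvalues()` provides Benjamini–Hochberg on
  request.
* The regression layer reports both large-sample z and small-sample t
  p values; at n ≈ 59 they differ slightly and neither is privileged.
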