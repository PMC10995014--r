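# cosinorHRV

Diurnal cosinor rhythmometry of ambulatory heart rate (HR) and vagally
mediated heart-rate variability (HRV, indexed by RMSSD), from raw
beat-to-beat interval recordings to two-group differential rhythmicity
tests.

Cardiac autonomic activity follows a roughly 24-hour pattern — HR dips and
vagal HRV peaks at night — and alterations of that pattern are of growing
interest in developmental psychiatry and chronobiology. This package
implements the full analysis chain used in ambulatory weekend-recording
studies of adolescent clinical groups: multi-day chest-belt inter-beat
interval (IBI) records are quality-controlled, segmented into 5-minute
windows, summarized as per-segment mean HR and RMSSD, and modelled with
fixed-period cosinor regression at the subject and group level. Because
clinical recordings of this kind are rarely shareable, the package also
ships a seeded synthetic cohort generator with known ground-truth rhythm
parameters, so every stage of the pipeline has a parameter-recovery test
surface.

## The model

For each subject and outcome (HR in bpm, RMSSD in ms), the single cosinor
model with fixed period τ = 24 h is fitted by ordinary least squares:

    Y(t) = M + A·cos(2πt/τ − φ) + e(t)
         = M + β·cos(2πt/τ) + γ·sin(2πt/τ) + e(t)

* **M (MESOR)** — Midline Estimating Statistic Of Rhythm, the
  rhythm-adjusted 24-h mean;
* **A (amplitude)** — distance from the MESOR to the peak of the cosine,
  `A = √(β² + γ²)`;
* **φ (acrophase)** — lag from local midnight to the peak,
  `φ = atan2(γ, β)` wrapped to `[0, 2π)`; `φ·24/(2π)` is the clock hour of
  the peak.

Rhythm detection is the zero-amplitude F test,
`F = ((TSS − RSS)/2)/(RSS/(n − 3))` on `(2, n − 3)` df. Group-level
summaries use the population-mean cosinor: individual coefficient vectors
`(M, β, γ)` are averaged, confidence intervals come from the among-subject
dispersion (Bingham-type variance components), and the group rhythm test
is a Hotelling-type F on `(β̄, γ̄)` with `(2, k − 2)` df. Two groups are
compared parameter by parameter on `(1, k₁ + k₂ − 2)` df; when the
acrophases differ significantly the amplitude comparison falls back to an
unpaired pooled-variance t test on the individual amplitudes, and Hedges'
g (bias-corrected standardized mean difference) is reported alongside.
Acrophase differences are circular (wrapped to `(−π, π]`) and convertible
to clock hours.

## Worked example

Fit a cosinor to 48 h of half-hourly observations with a known rhythm
(MESOR 80 bpm, amplitude 12 bpm, acrophase 1.81 rad):

```r
library(cosinorHRV)
set.seed(1)
t <- seq(0.5, 47.5, by = 0.5)      # hours since local midnight
y <- 80 + 12 * cos(2 * pi * t / 24 - 1.81) + rnorm(length(t), 0, 3)
fit <- cosinor_fit(t, y)
fit
#> Cosinor fit (period 24 h, n = 95)
#>   MESOR     80.44
#>   amplitude 12.31
#>   acrophase 1.765 rad (peak at 06:44)
zero_amplitude_test(fit)
#> 	Zero-amplitude rhythm detection test
#> F = 509.42, df1 = 2, df2 = 92, p-value < 2.2e-16
```

The estimates sit on the generating values within noise, and the rhythm
test overwhelmingly rejects a flat profile. The same machinery runs
end-to-end from raw IBIs: simulate a two-group cohort, preprocess,
summarize and compare:

```r
cfg <- pipeline_config(groups = list(rhythm_preset("nssi", 5),
                                     rhythm_preset("hc", 5)),
                       seed = 7, duration_hours = 24)
res <- run_pipeline(cfg, out_dir = "run1")
res$populations$HR[["NSSI"]]
#> Population-mean cosinor [NSSI] (k = 5, period 24 h)
#>           estimate   lower   upper
#> MESOR      84.6102 73.9155 95.3049
#> amplitude  10.0581  8.4125 11.7037
#> acrophase   1.6581  0.9575  2.3312
#> Rhythm detection: F(2, 3) = 111.18, p = 0.001536
res$comparisons$HR
#> Differential rhythmicity analysis: NSSI vs HC (HR)
#>   MESOR:     F(1, 8) = 2.50, p = 0.1527   Hedges' g = 0.90 [-0.41, 2.22]
#>   acrophase: F(1, 8) = 1.62, p = 0.2387   shift = 1.57 h
#>   amplitude: F(1, 8) = 4.33, p = 0.07113 (rhythm-parameter test)
```

The NSSI preset generates a group whose HR MESOR is ~6.5 bpm above the
control preset; with only 5 subjects per group (as here) the comparison
is underpowered, which is exactly what the printed p values show — the
full study design uses 29 and 30 subjects. `run1/` holds every stage
table (`segment_metrics.csv`, `cosinor_fits.csv`,
`population_cosinor.csv`, `comparison.csv`, `associations.csv`,
`quality.csv`) plus a JSON run manifest with the config hash and seed;
identical configs and seeds reproduce the outputs byte for byte.

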