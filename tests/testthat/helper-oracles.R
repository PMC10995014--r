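# Independent oracles and small builders used across the suite.

# brute-force cosinor: explicit 3x3 normal equations, no shared code with
# cosinor_fit beyond base solve()
oracle_cosinor <- function(time, value, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * time), sin(w * time))
  cf <- solve(t(X) %*% X, t(X) %*% value)
  b <- cf[2]; g <- cf[3]
  list(mesor = cf[1], beta = b, gamma = g,
       amplitude = sqrt(b^2 + g^2),
       acrophase = atan2(g, b) %% (2 * pi))
}

# dense-matrix evaluation of the smoothness-priors closed form
oracle_detrend <- function(values, lambda) {
  n <- length(values)
  D2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D2[i, i:(i + 2)] <- c(1, -2, 1)
  trend <- solve(diag(n) + lambda^2 * t(D2) %*% D2, values)
  values - drop(trend)
}

# constant-interval series builder (ms), gap-free
constant_series <- function(n, ibi = 1000, id = "t",
                            start = as.POSIXct("2019-06-01 10:00:00",
                                               tz = "UTC")) {
  ibi_series(id, start, ibi = rep(ibi, n))
}

# noise-free spec with a single rhythm and no between-subject spread
flat_spec <- function(hr_mesor = 70, hr_amplitude = 0, hr_acrophase = 0,
                      rmssd_mesor = 30, rmssd_amplitude = 0,
                      rmssd_acrophase = 0, n = 2, label = "G") {
  group_rhythm_spec(label, n,
                    hr_mesor = hr_mesor, hr_amplitude = hr_amplitude,
                    hr_acrophase = hr_acrophase,
                    rmssd_mesor = rmssd_mesor,
                    rmssd_amplitude = rmssd_amplitude,
                    rmssd_acrophase = rmssd_acrophase)
}

# fit a subject cosinor from parameter-level truth: sample n_points times
# over 48 h, evaluate the cosine, add iid noise, fit with cosinor_fit
fit_from_params <- function(mesor, amplitude, acrophase, noise_sd = 1,
                            n_points = 96, outcome = "HR") {
  t <- seq(10, 58, length.out = n_points)
  y <- mesor + amplitude * cos(2 * pi * t / 24 - acrophase) +
    rnorm(n_points, 0, noise_sd)
  cosinor_fit(t, y, outcome = outcome)
}

# a parameter-level cohort of k subject fits drawn around group means
cohort_fits <- function(k, mesor, amplitude, acrophase, mesor_sd = 8,
                        amp_sd = 4, acro_sd = 0.45, noise_sd = 1,
                        outcome = "HR") {
  lapply(seq_len(k), function(i) {
    fit_from_params(rnorm(1, mesor, mesor_sd),
                    max(0, rnorm(1, amplitude, amp_sd)),
                    (rnorm(1, acrophase, acro_sd)) %% (2 * pi),
                    noise_sd = noise_sd, outcome = outcome)
  })
}
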