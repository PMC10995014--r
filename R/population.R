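#' Population-mean cosinor
#'
#' Group-level rhythm summary obtained by averaging the individual cosinor
#' coefficient vectors `(M, beta, gamma)` over `k >= 3` subjects: the
#' population MESOR is the arithmetic mean of the individual MESORs, and
#' the population amplitude/acrophase derive from the averaged linear
#' coefficients. Confidence intervals follow the classical
#' population-mean-cosinor (Bingham-type) procedure, using the
#' among-subject dispersion of the coefficients; the acrophase interval is
#' undefined when the amplitude interval includes zero (the joint
#' confidence region then contains the origin). Rhythm detection is the
#' Hotelling-type F test of `(mean beta, mean gamma) = (0, 0)` on
#' `(2, k - 2)` degrees of freedom.
#'
#' @param fits list of [cosinor_fit] objects for one outcome, one per
#'   subject (all with the same period).
#' @param group_label label stored in the result.
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `population_cosinor`: list with `k`,
#'   `mesor`, `amplitude`, `acrophase`, their `ci` (2-column matrix),
#'   rhythm-detection `F`, `df`, `p.value`, the per-subject coefficient
#'   matrix `coefs`, `period`, `group_label`, `alpha`.
#' @export
population_cosinor <- function(fits, group_label = NA_character_, alpha = 0.05) {
  if (inherits(fits, "cosinor_fit")) fits <- list(fits)
  if (!all(vapply(fits, inherits, logical(1), "cosinor_fit"))) {
    stop("'fits' must be a list of cosinor_fit objects")
  }
  k <- length(fits)
  if (k < 3) stop("population-mean cosinor needs at least 3 subject fits")
  periods <- vapply(fits, `[[`, numeric(1), "period")
  if (length(unique(periods)) != 1) stop("all fits must share the same period")
  outcomes <- vapply(fits, function(f) as.character(f$outcome %||% NA), character(1))
  if (length(unique(outcomes[!is.na(outcomes)])) > 1) {
    stop("all fits must be for the same outcome")
  }

  coefs <- t(vapply(fits, function(f) c(mesor = f$mesor, beta = f$beta,
                                        gamma = f$gamma), numeric(3)))
  M <- mean(coefs[, "mesor"])
  beta <- mean(coefs[, "beta"]); gamma <- mean(coefs[, "gamma"])
  A <- sqrt(beta^2 + gamma^2)
  phi <- wrap_2pi(atan2(gamma, beta))

  v_m <- stats::var(coefs[, "mesor"])
  v_b <- stats::var(coefs[, "beta"])
  v_g <- stats::var(coefs[, "gamma"])
  c_bg <- stats::cov(coefs[, "beta"], coefs[, "gamma"])

  # Hotelling-type rhythm detection on the mean coefficient vector
  r2 <- c_bg^2 / (v_b * v_g)
  Fstat <- if (v_b > 0 && v_g > 0 && r2 < 1) {
    (k * (k - 2)) / (2 * (k - 1)) * (1 / (1 - r2)) *
      (beta^2 / v_b - 2 * c_bg * beta * gamma / (v_b * v_g) + gamma^2 / v_g)
  } else if (A > 0) Inf else 0
  p <- stats::pf(Fstat, 2, k - 2, lower.tail = FALSE)

  # Bingham-type variance components of the amplitude/acrophase estimates
  denom <- A^2 * k
  if (A > 0) {
    c22 <- (v_b * beta^2 + 2 * c_bg * beta * gamma + v_g * gamma^2) / denom
    c23 <- (-(v_b - v_g) * beta * gamma + c_bg * (beta^2 - gamma^2)) / denom
    c33 <- (v_b * gamma^2 - 2 * c_bg * beta * gamma + v_g * beta^2) / denom
  } else {
    c22 <- c23 <- c33 <- NA_real_
  }
  tq <- stats::qt(1 - alpha / 2, df = k - 1)
  ci_m <- M + c(-1, 1) * tq * sqrt(v_m / k)
  ci_a <- if (is.na(c22)) c(NA, NA) else A + c(-1, 1) * tq * sqrt(c22)
  if (!anyNA(ci_a) && ci_a[1] > 0 && c33 <= .Machine$double.eps) {
    ci_phi <- c(phi, phi)      # no among-subject dispersion at all
  } else if (!anyNA(ci_a) && ci_a[1] > 0) {
    disc <- A^2 - (c22 * c33 - c23^2) * tq^2 / c33
    ci_phi <- if (disc >= 0 && A^2 > c22 * tq^2) {
      phi + c(
        atan((c23 * tq^2 - tq * sqrt(c33) * sqrt(disc)) / (A^2 - c22 * tq^2)),
        atan((c23 * tq^2 + tq * sqrt(c33) * sqrt(disc)) / (A^2 - c22 * tq^2)))
    } else c(NA_real_, NA_real_)
  } else {
    ci_phi <- c(NA_real_, NA_real_)
  }

  ci <- rbind(mesor = ci_m, amplitude = ci_a, acrophase = ci_phi)
  colnames(ci) <- c("lower", "upper")
  structure(list(group_label = group_label, k = k,
                 mesor = M, amplitude = A, acrophase = phi,
                 beta = beta, gamma = gamma,
                 ci = ci, F = Fstat, df = c(2, k - 2), p.value = p,
                 coefs = coefs, var_components = c(c22 = c22, c23 = c23,
                                                   c33 = c33, v_m = v_m),
                 amplitudes = vapply(fits, `[[`, numeric(1), "amplitude"),
                 acrophases = vapply(fits, `[[`, numeric(1), "acrophase"),
                 period = periods[1], alpha = alpha,
                 outcome = unname(outcomes[which(!is.na(outcomes))[1]] %||% NA)),
            class = "population_cosinor")
}

#' @export
print.population_cosinor <- function(x, digits = 4, ...) {
  cat("Population-mean cosinor",
      if (!is.na(x$group_label)) paste0(" [", x$group_label, "]"),
      " (k = ", x$k, ", period ", x$period, " h)\n", sep = "")
  tab <- cbind(estimate = c(x$mesor, x$amplitude, x$acrophase), x$ci)
  rownames(tab) <- c("MESOR", "amplitude", "acrophase")
  print(round(tab, digits))
  cat(sprintf("Rhythm detection: F(%d, %d) = %.2f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p.value))
  invisible(x)
}

#' Two-group differential rhythmicity analysis
#'
#' Compares two population-mean cosinor summaries parameter by parameter,
#' each test on `(1, k1 + k2 - 2)` degrees of freedom. The MESOR test is
#' the classical one-way ANOVA F on the individual MESORs; the acrophase
#' test is a Wald-type F of the minimal circular difference between the
#' population acrophases against the sum of the two groups' Bingham
#' acrophase variance components.
#' When the acrophase test is significant at `alpha`, the amplitude
#' comparison via the rhythm-parameter test is unreliable, so amplitudes
#' are then compared by a pooled-variance unpaired t test on the
#' individual amplitudes; otherwise the Bingham amplitude F test is used.
#' Hedges' g (with 95% CI) is attached for MESOR and amplitude, and the
#' acrophase shift is reported in radians and clock hours.
#'
#' @param pop1,pop2 [population_cosinor] objects for the same outcome.
#' @param alpha significance level driving the amplitude-method switch.
#' @param amplitude_alternative sidedness of the amplitude t test
#'   (default `"two.sided"`).
#' @return An object of class `rhythm_comparison`.
#' @export
compare_rhythms <- function(pop1, pop2, alpha = 0.05,
                            amplitude_alternative = c("two.sided", "less",
                                                      "greater")) {
  stopifnot(inherits(pop1, "population_cosinor"),
            inherits(pop2, "population_cosinor"))
  amplitude_alternative <- match.arg(amplitude_alternative)
  o1 <- pop1$outcome; o2 <- pop2$outcome
  if (!is.na(o1) && !is.na(o2) && !identical(o1, o2)) {
    stop("populations are for different outcomes: ", o1, " vs ", o2)
  }
  k1 <- pop1$k; k2 <- pop2$k; K <- k1 + k2
  df2 <- K - 2

  # MESOR: one-way ANOVA on individual mesors
  m1 <- pop1$coefs[, "mesor"]; m2 <- pop2$coefs[, "mesor"]
  grand <- (k1 * mean(m1) + k2 * mean(m2)) / K
  ss_between <- k1 * (mean(m1) - grand)^2 + k2 * (mean(m2) - grand)^2
  ss_within <- ((k1 - 1) * stats::var(m1) + (k2 - 1) * stats::var(m2)) / df2
  F_mesor <- ss_between / ss_within
  p_mesor <- stats::pf(F_mesor, 1, df2, lower.tail = FALSE)

  # acrophase: Wald-type comparison of the population acrophases, with the
  # variance of each group's acrophase estimate taken from its Bingham
  # variance components (var(phi_hat) ~ c33 / A^2)
  phi1 <- pop1$acrophase; phi2 <- pop2$acrophase
  A1 <- pop1$amplitude; A2 <- pop2$amplitude
  V1 <- pop1$var_components[["c33"]] / A1^2
  V2 <- pop2$var_components[["c33"]] / A2^2
  F_acro <- circ_diff(phi1, phi2)^2 / (V1 + V2)
  p_acro <- stats::pf(F_acro, 1, df2, lower.tail = FALSE)

  shift_rad <- circ_diff(phi1, phi2)
  shift_h <- acrophase_diff_hours(phi1, phi2, pop1$period)

  # amplitude: t test on individual amplitudes when acrophases differ,
  # else Bingham amplitude F test
  a1 <- pop1$amplitudes; a2 <- pop2$amplitudes
  if (p_acro < alpha) {
    sp2 <- ((k1 - 1) * stats::var(a1) + (k2 - 1) * stats::var(a2)) / df2
    t_stat <- (mean(a1) - mean(a2)) / sqrt(sp2 * (1 / k1 + 1 / k2))
    p_amp <- switch(amplitude_alternative,
                    two.sided = 2 * stats::pt(abs(t_stat), df2, lower.tail = FALSE),
                    less = stats::pt(t_stat, df2),
                    greater = stats::pt(t_stat, df2, lower.tail = FALSE))
    amp_test <- list(method = "t_test", statistic = t_stat,
                     df = df2, p.value = p_amp)
  } else {
    F_amp <- (A1 - A2)^2 / (pop1$var_components[["c22"]] +
                              pop2$var_components[["c22"]])
    amp_test <- list(method = "bingham", statistic = F_amp, df = c(1, df2),
                     p.value = stats::pf(F_amp, 1, df2, lower.tail = FALSE))
  }

  structure(list(
    group_labels = c(pop1$group_label, pop2$group_label),
    outcome = o1 %||% o2, k = c(k1, k2),
    mesor_test = list(F = F_mesor, df = c(1, df2), p.value = p_mesor),
    acrophase_test = list(F = F_acro, df = c(1, df2), p.value = p_acro),
    amplitude_test = amp_test,
    acrophase_shift = list(radians = shift_rad, hours = shift_h),
    mesor_g = hedges_g(m1, m2),
    amplitude_g = hedges_g(a1, a2),
    alpha = alpha),
    class = "rhythm_comparison")
}

#' @export
print.rhythm_comparison <- function(x, digits = 3, ...) {
  cat("Differential rhythmicity analysis: ",
      paste(x$group_labels, collapse = " vs "),
      if (!is.na(x$outcome)) paste0(" (", x$outcome, ")"),
      "\n", sep = "")
  cat(sprintf("  MESOR:     F(%d, %d) = %.2f, p = %.4g   Hedges' g = %.2f [%.2f, %.2f]\n",
              x$mesor_test$df[1], x$mesor_test$df[2], x$mesor_test$F,
              x$mesor_test$p.value, x$mesor_g$g, x$mesor_g$ci[1], x$mesor_g$ci[2]))
  cat(sprintf("  acrophase: F(%d, %d) = %.2f, p = %.4g   shift = %.2f h\n",
              x$acrophase_test$df[1], x$acrophase_test$df[2],
              x$acrophase_test$F, x$acrophase_test$p.value,
              x$acrophase_shift$hours))
  if (x$amplitude_test$method == "t_test") {
    cat(sprintf("  amplitude: t(%d) = %.2f, p = %.4g (unpaired t test; acrophases differ)\n",
                x$amplitude_test$df, x$amplitude_test$statistic,
                x$amplitude_test$p.value))
  } else {
    cat(sprintf("  amplitude: F(%d, %d) = %.2f, p = %.4g (rhythm-parameter test)\n",
                x$amplitude_test$df[1], x$amplitude_test$df[2],
                x$amplitude_test$statistic, x$amplitude_test$p.value))
  }
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' Pooled-SD Cohen's d times the small-sample correction
#' `J = 1 - 3/(4*df - 1)` with `df = n1 + n2 - 2`, plus a large-sample
#' 95% confidence interval.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return List with `g`, `ci` (length-2), `d`, `J`, `se`.
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))$g   # -0.8
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  if (sp == 0) {
    return(list(g = NA_real_, ci = c(NA_real_, NA_real_), d = NA_real_,
                J = NA_real_, se = NA_real_))
  }
  d <- (mean(x) - mean(y)) / sp
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
  list(g = g, ci = g + c(-1, 1) * stats::qnorm(0.975) * se, d = d, J = J,
       se = se)
}

#' Acrophase difference in clock hours
#'
#' Signed minimal circular difference `phi1 - phi2` (wrapped to
#' `(-pi, pi]`) converted to hours for the given period.
#'
#' @param phi1,phi2 acrophases in radians.
#' @param period rhythm period in hours (default 24).
#' @return Signed difference in hours.
#' @examples
#' acrophase_diff_hours(5.02, 4.73)   # 1.108 h
#' @export
acrophase_diff_hours <- function(phi1, phi2, period = 24) {
  stopifnot_scalar(period, "period", positive = TRUE)
  circ_diff(phi1, phi2) * period / (2 * pi)
}

#' Convert an acrophase to clock time
#'
#' @param phi acrophase in radians, in `[0, 2*pi)`.
#' @param period rhythm period in hours (default 24).
#' @param reference clock hour of the phase reference (default 0 = local
#'   midnight).
#' @return Clock time in hours, wrapped to `[0, 24)`.
#' @examples
#' rad_to_clock(pi / 2)   # 6 (06:00)
#' @export
rad_to_clock <- function(phi, period = 24, reference = 0) {
  stopifnot_scalar(period, "period", positive = TRUE)
  (reference + phi * period / (2 * pi)) %% 24
}

#' Convert between peak-lag and classic negative-phase conventions
#'
#' The package reports acrophases as positive lags in `[0, 2*pi)` from the
#' reference time to the peak; the classic cosinor literature reports the
#' same angle with a negative sign in `(-2*pi, 0]`. This involution maps
#' each convention to the other.
#'
#' @param phi acrophase in radians.
#' @return The same acrophase in the opposite sign convention.
#' @export
acrophase_convention <- function(phi) {
  ifelse(phi > 0, phi - 2 * pi, ifelse(phi < 0, phi + 2 * pi, 0))
}
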