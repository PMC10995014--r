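#' Single-cosinor least-squares fit
#'
#' Fits the fixed-period cosinor model
#' \deqn{Y(t) = M + A \cos(2\pi t/\tau - \phi) + e(t)}
#' by ordinary least squares of `Y` on `cos(2*pi*t/tau)` and
#' `sin(2*pi*t/tau)`: with linear coefficients `beta` (cos) and `gamma`
#' (sin), the amplitude is `A = sqrt(beta^2 + gamma^2)` and the acrophase
#' `phi = atan2(gamma, beta)` wrapped to `[0, 2*pi)`. `M` (the MESOR) is
#' the rhythm-adjusted mean. Times may be irregular and gappy; the method
#' only needs at least 4 points that are not collinear in the design
#' (e.g. not all identical modulo the period).
#'
#' The default acrophase reference is local midnight when `time` is given
#' as clock hours, so `phi * tau / (2*pi)` is the clock time of the peak.
#'
#' @param time numeric vector of observation times in hours (e.g. hours
#'   since local midnight; values beyond 24 wrap naturally), or a formula
#'   `value ~ time`.
#' @param value numeric vector of observations (same length as `time`).
#' @param period fixed rhythm period `tau` in hours (default 24).
#' @param subject_id,outcome optional labels stored in the fit.
#' @param data,... for the formula method: a data frame holding the
#'   variables, and arguments passed on.
#' @return An object of class `cosinor_fit` with components `mesor`,
#'   `amplitude`, `acrophase`, `beta`, `gamma`, `period`, `n`,
#'   `df.residual`, `sigma2`, `tss`, `rss`, `vcov`, `fitted`, `residuals`,
#'   plus the inputs. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' t <- c(0, 6, 12, 18)
#' y <- 80 + 10 * cos(2 * pi * t / 24 - pi / 2)
#' fit <- cosinor_fit(t, y)
#' coef(fit)   # mesor 80, amplitude 10, acrophase pi/2 (peak 06:00)
#' @export
cosinor_fit <- function(time, ...) UseMethod("cosinor_fit")

#' @rdname cosinor_fit
#' @export
cosinor_fit.formula <- function(time, data, ...) {
  mf <- stats::model.frame(time, data = data)
  if (ncol(mf) != 2) stop("formula must be of the form value ~ time")
  cosinor_fit.default(mf[[2]], mf[[1]], ...)
}

#' @rdname cosinor_fit
#' @export
cosinor_fit.default <- function(time, value, period = 24, subject_id = NA_character_,
                                outcome = NA_character_, ...) {
  time <- as.numeric(time); value <- as.numeric(value)
  keep <- is.finite(time) & is.finite(value)
  time <- time[keep]; value <- value[keep]
  n <- length(time)
  if (length(value) != n) stop("'time' and 'value' lengths differ")
  if (n < 4) cosinor_failure("fewer than 4 usable observations")
  stopifnot_scalar(period, "period", positive = TRUE)
  if (diff(range(time)) <= period / 4) {
    cosinor_failure("observations must span at least a quarter period")
  }

  w <- 2 * pi / period
  X <- cbind(1, cos(w * time), sin(w * time))
  qx <- qr(X)
  if (qx$rank < 3) cosinor_failure("rank-deficient cosinor design")
  cf <- qr.coef(qx, value)
  fitted <- drop(X %*% cf)
  res <- value - fitted
  rss <- sum(res^2)
  tss <- sum((value - mean(value))^2)
  sigma2 <- rss / (n - 3)
  XtXinv <- chol2inv(qr.R(qx))

  beta <- cf[2]; gamma <- cf[3]
  structure(list(
    mesor = unname(cf[1]),
    amplitude = sqrt(beta^2 + gamma^2),
    acrophase = wrap_2pi(atan2(gamma, beta)),
    beta = unname(beta), gamma = unname(gamma),
    period = period, n = n, df.residual = n - 3L,
    sigma2 = sigma2, tss = tss, rss = rss,
    vcov = sigma2 * XtXinv,
    fitted = fitted, residuals = res,
    time = time, value = value,
    subject_id = subject_id, outcome = outcome,
    call = match.call()),
    class = "cosinor_fit")
}

cosinor_failure <- function(msg) {
  stop(structure(class = c("cosinor_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Zero-amplitude rhythm-detection test
#'
#' F test of the null hypothesis that the fitted cosine has zero amplitude
#' (no rhythm): `F = ((TSS - RSS)/2) / (RSS/(n - 3))` on `(2, n - 3)`
#' degrees of freedom. A perfect fit (`RSS = 0`) reports an infinite F
#' with p = 0.
#'
#' @param fit a [cosinor_fit].
#' @return An object of class `htest` with the F statistic, degrees of
#'   freedom and upper-tail p value.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  df1 <- 2; df2 <- fit$df.residual
  if (fit$tss <= .Machine$double.eps) {
    stat <- 0; p <- 1          # constant data: no rhythm, no variance
  } else if (fit$rss <= .Machine$double.eps * fit$tss) {
    stat <- Inf; p <- 0
  } else {
    stat <- ((fit$tss - fit$rss) / df1) / (fit$rss / df2)
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = c(F = stat),
                 parameter = c(df1 = df1, df2 = df2),
                 p.value = p,
                 method = "Zero-amplitude rhythm detection test",
                 data.name = paste0("cosinor fit (n = ", fit$n, ")")),
            class = "htest")
}

#' @export
coef.cosinor_fit <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase = object$acrophase, beta = object$beta, gamma = object$gamma)
}

#' @export
vcov.cosinor_fit <- function(object, ...) {
  v <- object$vcov
  dimnames(v) <- list(c("mesor", "beta", "gamma"), c("mesor", "beta", "gamma"))
  v
}

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' @param newdata optional numeric vector of times (hours) at which to
#'   evaluate the fitted cosine; defaults to the fitting times.
#' @rdname cosinor_fit
#' @export
predict.cosinor_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else as.numeric(newdata)
  object$mesor + object$amplitude *
    cos(2 * pi * t / object$period - object$acrophase)
}

#' @export
simulate.cosinor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- replicate(nsim, mu + stats::rnorm(object$n, 0, sqrt(object$sigma2)),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  cat("Cosinor fit (period ", x$period, " h, n = ", x$n, ")\n", sep = "")
  if (!is.na(x$subject_id)) cat("  subject: ", x$subject_id,
                                if (!is.na(x$outcome)) paste0(" / ", x$outcome),
                                "\n", sep = "")
  cat(sprintf("  MESOR     %.*g\n  amplitude %.*g\n  acrophase %.*g rad (peak at %s)\n",
              digits, x$mesor, digits, x$amplitude, digits, x$acrophase,
              format_clock(rad_to_clock(x$acrophase, x$period))))
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  # delta-method SEs for amplitude and acrophase
  b <- object$beta; g <- object$gamma; A <- object$amplitude
  if (A > 0) {
    dA <- c(0, b / A, g / A)
    dphi <- c(0, -g / A^2, b / A^2)
    seA <- sqrt(drop(t(dA) %*% object$vcov %*% dA))
    sephi <- sqrt(drop(t(dphi) %*% object$vcov %*% dphi))
  } else {
    seA <- sephi <- NA_real_
  }
  zt <- zero_amplitude_test(object)
  out <- list(fit = object,
              coef_table = data.frame(
                estimate = c(object$mesor, A, object$acrophase),
                se = c(se[1], seA, sephi),
                row.names = c("mesor", "amplitude", "acrophase")),
              rhythm_test = zt)
  class(out) <- "summary.cosinor_fit"
  out
}

#' @export
print.summary.cosinor_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  print(round(x$coef_table, digits))
  cat(sprintf("\nZero-amplitude test: F(%d, %d) = %.3f, p = %.4g\n",
              x$rhythm_test$parameter[["df1"]],
              x$rhythm_test$parameter[["df2"]],
              x$rhythm_test$statistic, x$rhythm_test$p.value))
  invisible(x)
}

#' @export
plot.cosinor_fit <- function(x, ...) {
  graphics::plot(x$time, x$value, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "time (h)", ylab = x$outcome %||% "value",
                 main = "Cosinor fit", ...)
  tt <- seq(min(x$time), max(x$time), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = x$mesor, lty = 2, col = "firebrick")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

format_clock <- function(h) {
  h <- h %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60) %% 60)
}
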