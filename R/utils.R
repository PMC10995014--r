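#' Wrap an angle to the half-open interval [0, 2*pi)
#'
#' @param phi numeric vector of angles in radians.
#' @return numeric vector of the same length, each element in `[0, 2*pi)`.
#' @keywords internal
wrap_2pi <- function(phi) {
  out <- phi %% (2 * pi)
  # guard against 2*pi returned by floating-point modulo of tiny negatives
  out[out >= 2 * pi] <- 0
  out
}

#' Signed minimal circular difference
#'
#' Difference `phi1 - phi2` wrapped to the interval `(-pi, pi]`.
#'
#' @param phi1,phi2 angles in radians.
#' @return signed difference in radians, in `(-pi, pi]`.
#' @keywords internal
circ_diff <- function(phi1, phi2) {
  d <- (phi1 - phi2) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# z-score a numeric vector; constant vectors raise an error naming the column
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant or degenerate column '", name, "'")
  }
  (x - mean(x)) / s
}

# derive a per-unit seed from a master seed, staying inside 32-bit range
derive_seed <- function(seed, index) {
  (as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483647
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop("'", name, "' must be > 0")
  invisible(x)
}
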