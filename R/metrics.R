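#' Root mean square of successive differences
#'
#' Time-domain vagal HRV index: each successive difference between
#' intervals is squared, the squares are averaged, and the square root of
#' the average is returned. Shift-invariant and non-negative.
#'
#' @param ibis numeric vector of inter-beat intervals (ms), length >= 2.
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 810, 790, 805))  # 15.546
#' @export
rmssd <- function(ibis) {
  ibis <- as.numeric(ibis)
  if (length(ibis) < 2) stop("RMSSD needs at least 2 intervals")
  sqrt(mean(diff(ibis)^2))
}

#' Mean heart rate of a set of intervals
#'
#' Average of the instantaneous per-beat heart rates `60000/ibi` (the
#' convention of common HRV toolchains), not `60000/mean(ibi)`.
#'
#' @param ibis numeric vector of inter-beat intervals (ms), length >= 1.
#' @param per_beat if `FALSE`, use `60000/mean(ibis)` instead.
#' @return Mean heart rate in bpm.
#' @export
mean_hr <- function(ibis, per_beat = TRUE) {
  ibis <- as.numeric(ibis)
  if (!length(ibis)) stop("mean_hr needs at least 1 interval")
  if (per_beat) mean(60000 / ibis) else 60000 / mean(ibis)
}

#' Per-segment HR and RMSSD
#'
#' Attaches `mean_hr` (bpm) and `rmssd` (ms) to every valid segment of a
#' grid. Both metrics use only the segment's longest consecutive run of
#' non-rejected beats; mean HR is computed on the raw intervals, RMSSD on
#' the smoothness-priors-detrended intervals (so slow within-segment
#' trends do not inflate the vagal index). Invalid segments carry `NA`.
#'
#' @param grid a [segment_ibi] result (carries its series and config).
#' @return The grid with `mean_hr` and `rmssd` columns added; class
#'   `segment_metrics`.
#' @export
compute_segment_metrics <- function(grid) {
  stopifnot(inherits(grid, "segment_grid"))
  series <- attr(grid, "series")
  config <- attr(grid, "config")
  len <- config$segment_length
  hr <- rep(NA_real_, nrow(grid))
  rm <- rep(NA_real_, nrow(grid))
  for (i in which(grid$valid)) {
    w <- (grid$day_index[i] - 1L) * floor(86400 / len) + grid$segment_index[i]
    run <- longest_run_indices(series, config, w)
    if (length(run) < 2) next
    ib <- series$beats$ibi[run]
    hr[i] <- mean_hr(ib)
    rm[i] <- if (length(ib) >= 3) {
      rmssd(detrend_segment(ib, config$detrend_lambda))
    } else {
      rmssd(ib)
    }
  }
  grid$mean_hr <- hr
  grid$rmssd <- rm
  class(grid) <- c("segment_metrics", class(grid))
  grid
}
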