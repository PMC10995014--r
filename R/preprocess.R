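#' Preprocessing configuration
#'
#' Bundles the quality-control parameters applied to raw IBI series.
#'
#' @param hr_min,hr_max plausibility bounds on instantaneous heart rate
#'   (bpm); beats with `60000/ibi` strictly outside `(hr_min, hr_max)` are
#'   rejected. Defaults 30 and 200.
#' @param detrend_lambda smoothness-priors regularization parameter
#'   (unitless, default 500) applied per segment before RMSSD.
#' @param segment_length segment length in seconds (default 300, i.e.
#'   5-minute segments, at most 288 per 24-h day).
#' @param min_consecutive minimum seconds of consecutive valid IBI data a
#'   segment must contain to be analysed (default 30).
#' @param ectopic_threshold relative deviation from the local median beyond
#'   which a beat is treated as ectopic and corrected (default 0.20).
#' @param max_corrected_fraction if more than this fraction of beats in any
#'   segment-length window is corrected, the whole window is rejected
#'   (default 0.05).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(hr_min = 30, hr_max = 200, detrend_lambda = 500,
                              segment_length = 300, min_consecutive = 30,
                              ectopic_threshold = 0.20,
                              max_corrected_fraction = 0.05) {
  for (nm in c("hr_min", "hr_max", "detrend_lambda", "segment_length",
               "min_consecutive", "ectopic_threshold",
               "max_corrected_fraction")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  if (hr_min >= hr_max) stop("'hr_min' must be below 'hr_max'")
  structure(list(hr_min = hr_min, hr_max = hr_max,
                 detrend_lambda = detrend_lambda,
                 segment_length = segment_length,
                 min_consecutive = min_consecutive,
                 ectopic_threshold = ectopic_threshold,
                 max_corrected_fraction = max_corrected_fraction),
            class = "preprocess_config")
}

#' Reject physiologically implausible beats
#'
#' Flags as `"rejected"` every beat whose instantaneous heart rate
#' `60000/ibi` lies strictly below `hr_min` or strictly above `hr_max`
#' (beats exactly at a bound are retained). Other beats are untouched, so
#' the operation is idempotent.
#'
#' @param series an [ibi_series].
#' @param config a [preprocess_config].
#' @return The series with updated flags.
#' @export
filter_implausible <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "ibi_series"))
  hr <- 60000 / series$beats$ibi
  bad <- hr < config$hr_min | hr > config$hr_max
  series$beats$flag[bad] <- "rejected"
  series
}

#' Automated ectopic-beat correction
#'
#' Surrogate for manual R-peak correction: a non-rejected beat whose IBI
#' deviates from the running median of its centred 11-beat neighbourhood by
#' more than `ectopic_threshold` (relative) is flagged `"corrected"` and
#' its IBI replaced by a cubic-spline interpolation through the surrounding
#' unflagged beats. If more than `max_corrected_fraction` of the beats in
#' any segment-length window had to be corrected, every beat in that window
#' is rejected instead.
#'
#' @param series an [ibi_series] (normally after [filter_implausible]).
#' @param config a [preprocess_config].
#' @return The series with corrected IBI values and updated flags.
#' @export
correct_ectopic <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "ibi_series"))
  idx <- which(series$beats$flag != "rejected")
  if (length(idx) < 11) {
    warning("series shorter than the correction neighbourhood; returned unchanged")
    return(series)
  }
  x <- series$beats$ibi[idx]
  med <- stats::runmed(x, k = 11, endrule = "median")
  dev <- abs(x - med) / med
  ect <- dev > config$ectopic_threshold
  if (any(ect)) {
    good <- which(!ect)
    if (length(good) >= 4) {
      repl <- stats::spline(good, x[good], xout = which(ect),
                            method = "natural")$y
      series$beats$ibi[idx[ect]] <- repl
    }
    series$beats$flag[idx[ect]] <- "corrected"
    # beat times are left untouched: correction edits values and flags only
  }
  # window-level rejection when too much correction was needed
  win <- floor(series$beats$t / config$segment_length)
  for (w in unique(win)) {
    sel <- win == w & series$beats$flag != "rejected"
    n <- sum(sel)
    if (n > 0 && sum(series$beats$flag[sel] == "corrected") / n >
        config$max_corrected_fraction) {
      series$beats$flag[win == w] <- "rejected"
    }
  }
  series
}

#' Smoothness-priors detrending
#'
#' Removes the slow trend from a short stationary-ish series by the
#' second-difference-penalized smoother: with `D2` the second-difference
#' operator, the trend is `(I + lambda^2 * t(D2) %*% D2)^{-1} %*% z` and
#' the detrended series is `z` minus that trend. Constant and linear
#' inputs lie in the smoother's null space and return (numerically) zeros.
#' The solve uses a sparse banded Cholesky factorization.
#'
#' @param values numeric vector (length >= 3), e.g. the IBIs of one
#'   segment in ms.
#' @param lambda regularization parameter (unitless, default 500).
#' @return Numeric vector: the detrended (stationary) component, same
#'   length as `values`.
#' @export
detrend_segment <- function(values, lambda = 500) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("detrending needs at least 3 values")
  stopifnot_scalar(lambda, "lambda", positive = TRUE)
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, values))
  values - trend
}

#' Clock-aligned segmentation
#'
#' Splits a preprocessed series into contiguous segment-length windows from
#' the recording start (at most 288 five-minute segments per 24-h day).
#' A segment's `covered` value is the duration (s) of the longest run of
#' consecutive non-rejected beats inside the window (sum of their IBIs);
#' the segment is `valid` iff `covered >= min_consecutive`.
#'
#' @param series an [ibi_series] after filtering/correction.
#' @param config a [preprocess_config].
#' @return An object of class `segment_grid`: a data frame with one row
#'   per segment and columns `subject_id`, `day_index`, `segment_index`
#'   (0-based within day), `clock_midpoint` (hours since local midnight),
#'   `time_midpoint` (hours since recording start), `n_beats`, `covered`
#'   (s) and `valid`; the series and config travel along as attributes.
#' @export
segment_ibi <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "ibi_series"))
  len <- config$segment_length
  t <- series$beats$t
  n_seg <- if (length(t)) ceiling(max(t) / len) else 0L
  per_day <- floor(86400 / len)
  clock0 <- start_clock_hours(series)

  win <- if (length(t)) pmin(floor(t / len), n_seg - 1) else integer(0)
  ok <- series$beats$flag != "rejected"

  rows <- lapply(seq_len(n_seg) - 1L, function(w) {
    sel <- which(win == w)
    covered <- 0; nb <- length(sel)
    if (nb) {
      runs <- rle(ok[sel])
      if (any(runs$values)) {
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        covered <- max(vapply(which(runs$values), function(r) {
          sum(series$beats$ibi[sel[starts[r]:ends[r]]])
        }, numeric(1))) / 1000
      }
    }
    mid_h <- (w * len + len / 2) / 3600
    data.frame(subject_id = series$subject_id,
               day_index = w %/% per_day + 1L,
               segment_index = w %% per_day,
               clock_midpoint = (clock0 + mid_h) %% 24,
               time_midpoint = mid_h,
               n_beats = nb, covered = covered,
               valid = covered >= config$min_consecutive,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  if (is.null(grid)) {
    grid <- data.frame(subject_id = character(0), day_index = integer(0),
                       segment_index = integer(0), clock_midpoint = numeric(0),
                       time_midpoint = numeric(0), n_beats = integer(0),
                       covered = numeric(0), valid = logical(0))
  }
  attr(grid, "series") <- series
  attr(grid, "config") <- config
  class(grid) <- c("segment_grid", "data.frame")
  grid
}

# indices (into series$beats) of the longest consecutive non-rejected run
# inside window w (0-based)
longest_run_indices <- function(series, config, w) {
  len <- config$segment_length
  t <- series$beats$t
  sel <- which(t >= w * len & t < (w + 1) * len)
  if (!length(sel)) return(integer(0))
  ok <- series$beats$flag[sel] != "rejected"
  runs <- rle(ok)
  if (!any(runs$values)) return(integer(0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  lens <- vapply(which(runs$values), function(r) {
    sum(series$beats$ibi[sel[starts[r]:ends[r]]])
  }, numeric(1))
  r <- which(runs$values)[which.max(lens)]
  sel[starts[r]:ends[r]]
}

#' One-call preprocessing
#'
#' Applies [filter_implausible], [correct_ectopic] and [segment_ibi] in
#' sequence.
#'
#' @inheritParams segment_ibi
#' @return A [segment_ibi] grid.
#' @export
preprocess_ibi <- function(series, config = preprocess_config()) {
  series <- filter_implausible(series, config)
  series <- suppressWarnings(correct_ectopic(series, config))
  segment_ibi(series, config)
}

#' Per-subject data-quality summary
#'
#' @param grid a [segment_ibi] result.
#' @param gap_threshold gap length (s) above which inter-beat silence
#'   counts as sensor non-wear (default 60).
#' @return One-row data frame: beats read / rejected / corrected, valid
#'   segments per day and in total, and non-wear minutes inferred from
#'   gaps longer than `gap_threshold`.
#' @export
quality_summary <- function(grid, gap_threshold = 60) {
  series <- attr(grid, "series")
  fl <- series$beats$flag
  gaps <- series$beats$ibi[fl == "rejected"] / 1000
  nonwear_min <- sum(gaps[gaps > gap_threshold]) / 60
  out <- data.frame(subject_id = series$subject_id,
                    n_beats = length(fl),
                    n_rejected = sum(fl == "rejected"),
                    n_corrected = sum(fl == "corrected"),
                    valid_segments = sum(grid$valid),
                    nonwear_minutes = nonwear_min,
                    valid_day1 = sum(grid$valid[grid$day_index == 1]),
                    valid_day2 = sum(grid$valid[grid$day_index == 2]),
                    stringsAsFactors = FALSE)
  out
}
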