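#' Draw one subject's ground-truth parameters
#'
#' Samples the six individual cosinor parameters from normal laws around the
#' group means with the group between-subject SDs (amplitudes truncated at
#' zero, acrophases wrapped to `[0, 2*pi)`), plus covariates from the
#' spec's covariate presets.
#'
#' @param spec a [group_rhythm_spec].
#' @param seed integer seed; the same seed reproduces the same subject.
#' @param subject_id identifier stored in the result.
#' @return An object of class `subject_truth`: a list with the six cosinor
#'   parameters, a named numeric `covariates` vector, `group_label`,
#'   `subject_id` and the `seed` used.
#' @export
sample_subject_truth <- function(spec, seed, subject_id = paste0(spec$group_label, "_01")) {
  if (!inherits(spec, "group_rhythm_spec")) {
    stop("'spec' must be a group_rhythm_spec")
  }
  set.seed(as.integer(seed))
  draw <- function(mean, sd) if (sd > 0) stats::rnorm(1, mean, sd) else mean
  hr_mesor <- draw(spec$hr_mesor, spec$hr_mesor_sd)
  hr_amplitude <- max(0, draw(spec$hr_amplitude, spec$hr_amplitude_sd))
  hr_acrophase <- wrap_2pi(draw(spec$hr_acrophase, spec$hr_acrophase_sd))
  rmssd_mesor <- draw(spec$rmssd_mesor, spec$rmssd_mesor_sd)
  rmssd_amplitude <- max(0, draw(spec$rmssd_amplitude, spec$rmssd_amplitude_sd))
  rmssd_acrophase <- wrap_2pi(draw(spec$rmssd_acrophase, spec$rmssd_acrophase_sd))
  covs <- vapply(spec$covariates, function(ms) max(0, draw(ms[1], ms[2])),
                 numeric(1))
  structure(list(subject_id = subject_id, group_label = spec$group_label,
                 hr_mesor = hr_mesor, hr_amplitude = hr_amplitude,
                 hr_acrophase = hr_acrophase, rmssd_mesor = rmssd_mesor,
                 rmssd_amplitude = rmssd_amplitude,
                 rmssd_acrophase = rmssd_acrophase,
                 covariates = covs, seed = as.integer(seed)),
            class = "subject_truth")
}

# instantaneous HR (bpm) and RMSSD target (ms) at clock hour(s) h
truth_hr <- function(truth, h) {
  truth$hr_mesor + truth$hr_amplitude * cos(2 * pi * h / 24 - truth$hr_acrophase)
}
truth_rmssd <- function(truth, h, floor_ms = 0) {
  pmax(floor_ms,
       truth$rmssd_mesor +
         truth$rmssd_amplitude * cos(2 * pi * h / 24 - truth$rmssd_acrophase))
}

#' Simulate a beat-to-beat interval recording
#'
#' Generates a synthetic ambulatory IBI record whose instantaneous heart
#' rate follows the subject's 24-h cosine,
#' `HR(t) = M + A * cos(2*pi*t/24 - phi)` with `t` in clock hours since
#' local midnight. Base beat times are obtained by inverting the cumulative
#' beat-count function of that rate; each interval then receives an
#' independent zero-mean Gaussian perturbation with per-beat SD
#' `sigma(t) = RMSSD_target(t) / sqrt(2)`, so the expected RMSSD of the
#' clean series equals the target (for iid perturbations,
#' `E[RMSSD] = sqrt(2) * sigma`). Ectopic events are injected as a
#' premature beat at 0.6 times the local interval followed by a
#' compensatory pause that restores cumulative time; beats inside non-wear
#' windows are deleted (the gap surfaces as one long interval, rejected by
#' the downstream plausibility filter).
#'
#' @param truth a [sample_subject_truth] result.
#' @param duration_hours recording length in hours (> 0); default 48.
#' @param artifacts an [artifact_spec].
#' @param seed integer seed for the beat-level noise and artifact draws.
#' @param start_time `POSIXct` recording start; the default is a Saturday
#'   10:00 morning start, the protocol this generator emulates.
#' @return An [ibi_series].
#' @export
simulate_ibi <- function(truth, duration_hours = 48,
                         artifacts = artifact_spec(), seed = NULL,
                         start_time = as.POSIXct("2019-06-01 10:00:00",
                                                 tz = "UTC")) {
  if (!inherits(truth, "subject_truth")) stop("'truth' must be a subject_truth")
  if (!inherits(artifacts, "artifact_spec")) {
    stop("'artifacts' must be an artifact_spec")
  }
  stopifnot_scalar(duration_hours, "duration_hours", positive = TRUE)
  if (truth$hr_mesor - truth$hr_amplitude <= 0) {
    stop("rhythm parameters imply non-positive instantaneous heart rate")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  lt <- as.POSIXlt(start_time)
  clock0 <- lt$hour + lt$min / 60 + lt$sec / 3600

  # cumulative beat count Lambda(u) for u hours since recording start:
  # integral of HR (beats/min) * 60, closed form for the cosine rate
  omega <- 2 * pi / 24
  Lambda <- function(u) {
    60 * (truth$hr_mesor * u +
            truth$hr_amplitude / omega *
              (sin(omega * (clock0 + u) - truth$hr_acrophase) -
                 sin(omega * clock0 - truth$hr_acrophase)))
  }
  n_beats <- floor(Lambda(duration_hours))
  if (n_beats < 2) stop("duration too short to generate beats")
  grid <- seq(0, duration_hours, length.out = max(2L, ceiling(duration_hours * 3600)))
  t_beat_h <- stats::approx(Lambda(grid), grid, xout = seq_len(n_beats))$y

  base_ibi <- diff(c(0, t_beat_h)) * 3600 * 1000           # ms
  sigma <- truth_rmssd(truth, clock0 + t_beat_h,
                       floor_ms = artifacts$iid_noise_floor) / sqrt(2)
  ibi <- base_ibi + stats::rnorm(n_beats, 0, sigma)
  ibi <- pmax(ibi, 1)                                      # physical floor

  # ectopy: premature beat + compensatory pause, cumulative time preserved
  if (artifacts$ectopic_rate > 0) {
    cand <- which(stats::runif(n_beats) < artifacts$ectopic_rate)
    cand <- cand[cand < n_beats - 1]
    cand <- cand[c(TRUE, diff(cand) > 2)]                  # no overlapping pairs
    if (length(cand)) {
      premature <- 0.6 * ibi[cand]
      ibi[cand + 1] <- ibi[cand + 1] + (ibi[cand] - premature)
      ibi[cand] <- premature
    }
  }

  t_sec <- cumsum(ibi) / 1000
  keep <- t_sec <= duration_hours * 3600   # noise may push the tail over
  for (w in artifacts$nonwear_windows) {
    keep <- keep & !(t_sec > w[1] * 3600 & t_sec < (w[1] + w[2]) * 3600)
  }
  t_sec <- t_sec[keep]
  ibi <- diff(c(0, t_sec)) * 1000   # gaps absorbed into the next interval

  ibi_series(truth$subject_id, start_time, ibi = ibi, t = t_sec)
}

#' Simulate a multi-group cohort
#'
#' Draws each subject's ground truth from its group spec, simulates one
#' IBI recording per subject, and assembles the metadata table (group
#' label, ground-truth cosinor parameters, covariates, seeds). All
#' randomness derives deterministically from `seed`.
#'
#' @param specs list of [group_rhythm_spec] objects (>= 1).
#' @param artifacts an [artifact_spec] applied to every subject.
#' @param seed master integer seed.
#' @param duration_hours recording length per subject; default 48.
#' @param out_dir optional directory; when given, one IBI file per subject
#'   (`<subject_id>.ibi.txt`) and `metadata.csv` are written there.
#' @param start_time recording start timestamp (shared by all subjects).
#' @return A list with `series` (named list of [ibi_series]), `truths`
#'   (named list of subject truths) and `metadata` (data frame, one row per
#'   subject).
#' @export
simulate_cohort <- function(specs, artifacts = artifact_spec(), seed = 1,
                            duration_hours = 48, out_dir = NULL,
                            start_time = as.POSIXct("2019-06-01 10:00:00",
                                                    tz = "UTC")) {
  if (inherits(specs, "group_rhythm_spec")) specs <- list(specs)
  if (!length(specs)) stop("at least one group spec is required")
  if (!all(vapply(specs, inherits, logical(1), "group_rhythm_spec"))) {
    stop("'specs' must be a list of group_rhythm_spec objects")
  }
  ids <- unlist(lapply(specs, function(s) {
    if (s$n_subjects == 0) character(0)
    else sprintf("%s_%02d", s$group_label, seq_len(s$n_subjects))
  }))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  }

  series <- list(); truths <- list(); meta <- list()
  counter <- 0L
  for (s in specs) {
    if (s$n_subjects == 0) next
    for (j in seq_len(s$n_subjects)) {
      counter <- counter + 1L
      id <- sprintf("%s_%02d", s$group_label, j)
      tr_seed <- derive_seed(seed, 2L * counter)
      sim_seed <- derive_seed(seed, 2L * counter + 1L)
      tr <- sample_subject_truth(s, tr_seed, subject_id = id)
      ser <- simulate_ibi(tr, duration_hours = duration_hours,
                          artifacts = artifacts, seed = sim_seed,
                          start_time = start_time)
      series[[id]] <- ser
      truths[[id]] <- tr
      meta[[id]] <- data.frame(
        subject_id = id, group_label = s$group_label,
        true_hr_mesor = tr$hr_mesor, true_hr_amplitude = tr$hr_amplitude,
        true_hr_acrophase = tr$hr_acrophase,
        true_rmssd_mesor = tr$rmssd_mesor,
        true_rmssd_amplitude = tr$rmssd_amplitude,
        true_rmssd_acrophase = tr$rmssd_acrophase,
        as.list(tr$covariates),
        truth_seed = tr_seed, sim_seed = sim_seed,
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(series)) {
      write_ibi(series[[id]], file.path(out_dir, paste0(id, ".ibi.txt")))
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(series = series, truths = truths, metadata = metadata)
}
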