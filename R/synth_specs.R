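#' Group-level rhythm specification for the synthetic cohort generator
#'
#' Describes one study group by the population means and between-subject
#' standard deviations of the six cosinor parameters that drive the
#' generator: MESOR, amplitude and acrophase of heart rate (HR, bpm) and of
#' RMSSD (ms). Acrophases are radians from local midnight with a 24-h
#' period. Covariate distributions (age, BMI, daily step count, sleep time,
#' and clinical severity scores) are normal laws given as `c(mean, sd)`.
#'
#' @param group_label character scalar naming the group.
#' @param n_subjects number of subjects to generate (>= 0; 0 = empty group).
#' @param hr_mesor,hr_amplitude,hr_acrophase group means of the HR cosinor
#'   parameters (bpm, bpm, radians).
#' @param rmssd_mesor,rmssd_amplitude,rmssd_acrophase group means of the
#'   RMSSD cosinor parameters (ms, ms, radians).
#' @param hr_mesor_sd,hr_amplitude_sd,hr_acrophase_sd,rmssd_mesor_sd,rmssd_amplitude_sd,rmssd_acrophase_sd
#'   between-subject standard deviations (same units as the means).
#' @param covariates named list of `c(mean, sd)` pairs; defaults are filled
#'   from [default_covariates()] for the given label.
#' @return An object of class `group_rhythm_spec` (a validated list).
#' @seealso [rhythm_preset()] for ready-made two-group presets.
#' @export
group_rhythm_spec <- function(group_label, n_subjects,
                              hr_mesor, hr_amplitude, hr_acrophase,
                              rmssd_mesor, rmssd_amplitude, rmssd_acrophase,
                              hr_mesor_sd = 0, hr_amplitude_sd = 0,
                              hr_acrophase_sd = 0, rmssd_mesor_sd = 0,
                              rmssd_amplitude_sd = 0, rmssd_acrophase_sd = 0,
                              covariates = NULL) {
  if (!is.character(group_label) || length(group_label) != 1L) {
    stop("'group_label' must be a character scalar")
  }
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 0 || n_subjects != round(n_subjects)) {
    stop("'n_subjects' must be a non-negative integer")
  }
  num <- list(hr_mesor = hr_mesor, hr_amplitude = hr_amplitude,
              hr_acrophase = hr_acrophase, rmssd_mesor = rmssd_mesor,
              rmssd_amplitude = rmssd_amplitude,
              rmssd_acrophase = rmssd_acrophase,
              hr_mesor_sd = hr_mesor_sd, hr_amplitude_sd = hr_amplitude_sd,
              hr_acrophase_sd = hr_acrophase_sd,
              rmssd_mesor_sd = rmssd_mesor_sd,
              rmssd_amplitude_sd = rmssd_amplitude_sd,
              rmssd_acrophase_sd = rmssd_acrophase_sd)
  for (nm in names(num)) stopifnot_scalar(num[[nm]], nm)
  if (hr_amplitude < 0 || rmssd_amplitude < 0) {
    stop("'hr_amplitude' and 'rmssd_amplitude' must be >= 0")
  }
  if (hr_acrophase < 0 || hr_acrophase >= 2 * pi ||
      rmssd_acrophase < 0 || rmssd_acrophase >= 2 * pi) {
    stop("acrophases must lie in [0, 2*pi)")
  }
  if (hr_mesor <= hr_amplitude) {
    stop("'hr_mesor' must exceed 'hr_amplitude' so instantaneous HR stays positive")
  }
  if (any(unlist(num[grep("_sd$", names(num))]) < 0)) {
    stop("between-subject standard deviations must be >= 0")
  }
  cov_def <- default_covariates(group_label)
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (!is.numeric(v) || length(v) != 2L || v[2] < 0) {
        stop("covariate '", nm, "' must be c(mean, sd) with sd >= 0")
      }
      cov_def[[nm]] <- v
    }
  }
  structure(c(list(group_label = group_label,
                   n_subjects = as.integer(n_subjects)),
              num, list(covariates = cov_def)),
            class = "group_rhythm_spec")
}

#' Default covariate distributions
#'
#' Normal `c(mean, sd)` presets for the subject-level covariates emitted by
#' the generator, keyed by group label. The `"NSSI"` and `"HC"` presets
#' mirror the descriptive statistics of a two-group female-adolescent
#' ambulatory study (clinical group with non-suicidal self-injury vs
#' healthy controls); any other label gets the healthy-control values.
#'
#' @param group_label character scalar.
#' @return Named list of length-2 numeric vectors: `age` (years),
#'   `bmi` (kg/m^2), `step_count` (steps/day), `sleep_time` (h),
#'   `elm_severity`, `bpd_symptoms`, `depressive_symptoms`,
#'   `emotion_dysregulation` (unitless severity scores).
#' @export
default_covariates <- function(group_label) {
  if (identical(toupper(group_label), "NSSI")) {
    list(age = c(15.10, 1.06), bmi = c(22.12, 4.94),
         step_count = c(11887, 7135.69), sleep_time = c(7.31, 3.25),
         elm_severity = c(11.24, 4.03), bpd_symptoms = c(3.87, 2.20),
         depressive_symptoms = c(25.52, 10.65),
         emotion_dysregulation = c(111.76, 23.36))
  } else {
    list(age = c(14.77, 1.52), bmi = c(20.02, 1.86),
         step_count = c(10226.62, 4694.02), sleep_time = c(7.64, 1.73),
         elm_severity = c(5.98, 1.26), bpd_symptoms = c(0.07, 0.25),
         depressive_symptoms = c(5.27, 3.04),
         emotion_dysregulation = c(54.30, 10.72))
  }
}

# chosen between-subject dispersions shared by both presets; see the methods
# vignette for the calibration rationale
.preset_sds <- list(hr_mesor_sd = 8, hr_amplitude_sd = 4, hr_acrophase_sd = 0.45,
                    rmssd_mesor_sd = 15, rmssd_amplitude_sd = 6,
                    rmssd_acrophase_sd = 0.45)

#' Ready-made group presets
#'
#' Two-group presets whose population-mean cosinor parameters reproduce the
#' group-level diurnal structure of a 48-h weekend ambulatory study of
#' female adolescents: a clinical NSSI group (higher HR MESOR, later
#' acrophases, lower RMSSD MESOR) and healthy controls. Between-subject
#' standard deviations are the package's documented choices (see the
#' methods vignette), not study-reported quantities.
#'
#' @param group `"nssi"` or `"hc"`.
#' @param n_subjects group size; defaults to 29 (nssi) / 30 (hc).
#' @return A [group_rhythm_spec].
#' @examples
#' rhythm_preset("nssi")$hr_mesor   # 85.98 bpm
#' @export
rhythm_preset <- function(group = c("nssi", "hc"), n_subjects = NULL) {
  group <- match.arg(group)
  if (group == "nssi") {
    if (is.null(n_subjects)) n_subjects <- 29
    do.call(group_rhythm_spec, c(list(
      group_label = "NSSI", n_subjects = n_subjects,
      hr_mesor = 85.98, hr_amplitude = 12.42, hr_acrophase = 1.81,
      rmssd_mesor = 44.82, rmssd_amplitude = 13.90, rmssd_acrophase = 5.02),
      .preset_sds))
  } else {
    if (is.null(n_subjects)) n_subjects <- 30
    do.call(group_rhythm_spec, c(list(
      group_label = "HC", n_subjects = n_subjects,
      hr_mesor = 79.44, hr_amplitude = 12.30, hr_acrophase = 1.56,
      rmssd_mesor = 55.79, rmssd_amplitude = 14.45, rmssd_acrophase = 4.73),
      .preset_sds))
  }
}

#' Artifact model for the IBI simulator
#'
#' @param ectopic_rate per-beat probability of injecting an ectopic event
#'   (premature beat plus compensatory pause); must lie in `[0, 0.1]`.
#' @param nonwear_windows list of `c(start_h, duration_h)` sensor-off
#'   windows in hours since recording start; windows must lie within
#'   `[0, 48]` and must not overlap.
#' @param iid_noise_floor lower bound (ms) on the per-beat RMSSD target, so
#'   the beat-level Gaussian perturbation never degenerates.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(ectopic_rate = 0, nonwear_windows = list(),
                          iid_noise_floor = 3) {
  stopifnot_scalar(ectopic_rate, "ectopic_rate")
  if (ectopic_rate < 0 || ectopic_rate > 0.1) {
    stop("'ectopic_rate' must lie in [0, 0.1]")
  }
  stopifnot_scalar(iid_noise_floor, "iid_noise_floor")
  if (iid_noise_floor < 0) stop("'iid_noise_floor' must be >= 0")
  if (length(nonwear_windows)) {
    w <- do.call(rbind, lapply(nonwear_windows, function(x) {
      if (!is.numeric(x) || length(x) != 2L || any(x < 0)) {
        stop("each non-wear window must be c(start_h, duration_h), both >= 0")
      }
      c(x[1], x[1] + x[2])
    }))
    if (any(w > 48)) stop("non-wear windows must lie within [0, 48] h")
    w <- w[order(w[, 1]), , drop = FALSE]
    if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2])) {
      stop("non-wear windows must not overlap")
    }
  }
  structure(list(ectopic_rate = ectopic_rate,
                 nonwear_windows = nonwear_windows,
                 iid_noise_floor = iid_noise_floor),
            class = "artifact_spec")
}
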