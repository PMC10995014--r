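#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic-cohort
#' analysis run: cohort composition, artifact model, preprocessing
#' parameters, fitting/exclusion rules and the master seed.
#'
#' @param groups list of [group_rhythm_spec] objects (e.g. from
#'   [rhythm_preset]); must contain at least one subject in total.
#' @param seed master integer seed; every stage derives its randomness
#'   from it.
#' @param duration_hours recording length per subject (default 48).
#' @param artifacts an [artifact_spec].
#' @param preprocess a [preprocess_config].
#' @param min_segments minimum number of valid segments a subject needs
#'   for their cosinor fit to be retained (default 48).
#' @param period cosinor period in hours (default 24).
#' @param days optional integer vector of measurement days (1 and/or 2) to
#'   restrict the cosinor fits to; `NULL` (default) pools both recording
#'   days into one fit per subject. Setting `days = 1` or `days = 2`
#'   reproduces the per-day sensitivity analysis.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = list(rhythm_preset("nssi", 8),
                                          rhythm_preset("hc", 8)),
                            seed = 1, duration_hours = 48,
                            artifacts = artifact_spec(),
                            preprocess = preprocess_config(),
                            min_segments = 48, period = 24, days = NULL) {
  if (inherits(groups, "group_rhythm_spec")) groups <- list(groups)
  if (!length(groups) ||
      !all(vapply(groups, inherits, logical(1), "group_rhythm_spec"))) {
    stop("'groups' must be a non-empty list of group_rhythm_spec objects")
  }
  if (sum(vapply(groups, `[[`, integer(1), "n_subjects")) == 0) {
    stop("configuration contains no subjects")
  }
  stopifnot_scalar(duration_hours, "duration_hours", positive = TRUE)
  stopifnot_scalar(min_segments, "min_segments", positive = TRUE)
  stopifnot_scalar(period, "period", positive = TRUE)
  stopifnot(inherits(artifacts, "artifact_spec"),
            inherits(preprocess, "preprocess_config"))
  structure(list(groups = groups, seed = as.integer(seed),
                 duration_hours = duration_hours, artifacts = artifacts,
                 preprocess = preprocess, min_segments = min_segments,
                 period = period, days = days),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config]: top-level `seed`,
#' `duration_hours`, `min_segments`, `period`; `groups` is a list whose
#' entries are either `preset: nssi|hc` (with optional `n_subjects`) or
#' the full argument set of [group_rhythm_spec]; `artifacts` and
#' `preprocess` hold the argument sets of [artifact_spec] and
#' [preprocess_config].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g) {
    if (!is.null(g$preset)) {
      rhythm_preset(g$preset, n_subjects = g$n_subjects)
    } else {
      do.call(group_rhythm_spec, g)
    }
  })
  art <- if (is.null(y$artifacts)) artifact_spec() else {
    if (!is.null(y$artifacts$nonwear_windows)) {
      y$artifacts$nonwear_windows <- lapply(y$artifacts$nonwear_windows, unlist)
    }
    do.call(artifact_spec, y$artifacts)
  }
  pp <- if (is.null(y$preprocess)) preprocess_config() else {
    do.call(preprocess_config, y$preprocess)
  }
  args <- y[intersect(names(y), c("seed", "duration_hours", "min_segments",
                                  "period", "days"))]
  do.call(pipeline_config, c(list(groups = groups, artifacts = art,
                                  preprocess = pp), args))
}

#' Fit one subject's cosinor models from segment metrics
#'
#' @param metrics a [compute_segment_metrics] table for one subject.
#' @param config a [pipeline_config] (for period and exclusion rule).
#' @param clock0 clock hour of the recording start.
#' @return Named list with `HR` and `RMSSD` [cosinor_fit] objects (either
#'   may be `NULL` when the subject fails the exclusion rule, with the
#'   reason in attribute `"exclusions"`).
#' @keywords internal
fit_subject <- function(metrics, config, clock0) {
  if (!is.null(config$days)) {
    metrics <- metrics[metrics$day_index %in% config$days, ]
  }
  valid <- metrics[metrics$valid & !is.na(metrics$mean_hr), ]
  exclusions <- character(0)
  out <- list(HR = NULL, RMSSD = NULL)
  if (nrow(valid) < config$min_segments) {
    exclusions <- paste0("only ", nrow(valid), " valid segments (< ",
                         config$min_segments, ")")
  } else {
    times <- clock0 + valid$time_midpoint
    for (oc in c("HR", "RMSSD")) {
      y <- if (oc == "HR") valid$mean_hr else valid$rmssd
      f <- tryCatch(
        cosinor_fit(times[!is.na(y)], y[!is.na(y)], period = config$period,
                    subject_id = metrics$subject_id[1], outcome = oc),
        cosinor_fit_error = function(e) {
          exclusions <<- c(exclusions, paste0(oc, ": ", conditionMessage(e)))
          NULL
        })
      out[[oc]] <- f
    }
  }
  attr(out, "exclusions") <- exclusions
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate -> preprocess -> segment metrics -> individual cosinor fits ->
#' population-mean cosinor per group -> two-group differential
#' rhythmicity -> group regressions, writing every stage table as CSV
#' plus a JSON run manifest (config hash, seed, stage row counts,
#' warnings). Reruns with identical config and seed produce identical
#' outputs.
#'
#' @param config a [pipeline_config] or the path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all stage results (`cohort`, `metrics`,
#'   `fits`, `subjects` table, `populations`, `comparisons`,
#'   `associations`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)

  cohort <- simulate_cohort(config$groups, artifacts = config$artifacts,
                            seed = config$seed,
                            duration_hours = config$duration_hours)
  utils::write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)

  metrics_list <- list(); quality <- list(); fits <- list()
  subject_rows <- list()
  for (id in names(cohort$series)) {
    ser <- cohort$series[[id]]
    grid <- preprocess_ibi(ser, config$preprocess)
    qs <- quality_summary(grid)
    sm <- compute_segment_metrics(grid)
    metrics_list[[id]] <- sm
    quality[[id]] <- qs
    sub <- fit_subject(sm, config, start_clock_hours(ser))
    excl <- attr(sub, "exclusions")
    if (length(excl)) {
      warnings_log <- c(warnings_log, paste0(id, ": ", excl))
    }
    fits[[id]] <- sub
    meta <- cohort$metadata[cohort$metadata$subject_id == id, ]
    row <- data.frame(subject_id = id, group_label = meta$group_label,
                      valid_segments = qs$valid_segments,
                      age = meta$age, bmi = meta$bmi,
                      step_count = meta$step_count,
                      sleep_time = meta$sleep_time,
                      elm_severity = meta$elm_severity,
                      bpd_symptoms = meta$bpd_symptoms,
                      depressive_symptoms = meta$depressive_symptoms,
                      emotion_dysregulation = meta$emotion_dysregulation,
                      stringsAsFactors = FALSE)
    for (oc in c("HR", "RMSSD")) {
      f <- sub[[oc]]
      pre <- tolower(oc)
      row[[paste0(pre, "_mesor")]] <- if (is.null(f)) NA_real_ else f$mesor
      row[[paste0(pre, "_amplitude")]] <- if (is.null(f)) NA_real_ else f$amplitude
      row[[paste0(pre, "_acrophase")]] <- if (is.null(f)) NA_real_ else f$acrophase
    }
    subject_rows[[id]] <- row
  }
  metrics_all <- do.call(rbind, lapply(metrics_list, as.data.frame))
  rownames(metrics_all) <- NULL
  utils::write.csv(metrics_all, file.path(out_dir, "segment_metrics.csv"),
                   row.names = FALSE)
  quality_all <- do.call(rbind, quality)
  rownames(quality_all) <- NULL
  utils::write.csv(quality_all, file.path(out_dir, "quality.csv"),
                   row.names = FALSE)
  subjects <- do.call(rbind, subject_rows)
  rownames(subjects) <- NULL
  utils::write.csv(subjects, file.path(out_dir, "cosinor_fits.csv"),
                   row.names = FALSE)

  # population-mean cosinor per group and outcome, plus two-group comparison
  labels <- unique(subjects$group_label)
  populations <- list(); comparisons <- list()
  pop_rows <- list(); cmp_rows <- list()
  for (oc in c("HR", "RMSSD")) {
    pops <- list()
    for (lab in labels) {
      ids <- subjects$subject_id[subjects$group_label == lab]
      fl <- Filter(Negate(is.null), lapply(fits[ids], `[[`, oc))
      if (length(fl) >= 3) {
        pops[[lab]] <- population_cosinor(fl, group_label = lab)
        p <- pops[[lab]]
        pop_rows[[paste(oc, lab)]] <- data.frame(
          outcome = oc, group = lab, k = p$k, mesor = p$mesor,
          mesor_lo = p$ci["mesor", 1], mesor_hi = p$ci["mesor", 2],
          amplitude = p$amplitude,
          amplitude_lo = p$ci["amplitude", 1],
          amplitude_hi = p$ci["amplitude", 2],
          acrophase = p$acrophase,
          acrophase_lo = p$ci["acrophase", 1],
          acrophase_hi = p$ci["acrophase", 2],
          rhythm_F = p$F, rhythm_df1 = p$df[1], rhythm_df2 = p$df[2],
          rhythm_p = p$p.value, stringsAsFactors = FALSE)
      }
    }
    populations[[oc]] <- pops
    if (length(pops) >= 2) {
      cmp <- compare_rhythms(pops[[1]], pops[[2]])
      comparisons[[oc]] <- cmp
      cmp_rows[[oc]] <- data.frame(
        outcome = oc,
        group1 = cmp$group_labels[1], group2 = cmp$group_labels[2],
        mesor_F = cmp$mesor_test$F, mesor_df2 = cmp$mesor_test$df[2],
        mesor_p = cmp$mesor_test$p.value,
        mesor_g = cmp$mesor_g$g,
        mesor_g_lo = cmp$mesor_g$ci[1], mesor_g_hi = cmp$mesor_g$ci[2],
        acrophase_F = cmp$acrophase_test$F,
        acrophase_p = cmp$acrophase_test$p.value,
        acrophase_shift_h = cmp$acrophase_shift$hours,
        amplitude_method = cmp$amplitude_test$method,
        amplitude_stat = cmp$amplitude_test$statistic,
        amplitude_p = cmp$amplitude_test$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(pop_rows)) {
    utils::write.csv(do.call(rbind, pop_rows),
                     file.path(out_dir, "population_cosinor.csv"),
                     row.names = FALSE)
  }
  if (length(cmp_rows)) {
    utils::write.csv(do.call(rbind, cmp_rows),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }

  # group-predictor regressions on the fitted cosinor parameters
  assoc_rows <- list()
  if (length(labels) >= 2) {
    cos_cols <- c("hr_mesor", "hr_amplitude", "hr_acrophase",
                  "rmssd_mesor", "rmssd_amplitude", "rmssd_acrophase")
    for (oc in cos_cols) {
      for (adj in c(FALSE, TRUE)) {
        r <- tryCatch(
          fit_univariate_models(subjects, oc, "group_label", adjust = adj),
          error = function(e) {
            warnings_log <<- c(warnings_log,
                               paste0("association ", oc, ": ",
                                      conditionMessage(e)))
            NULL
          })
        if (is.null(r)) next
        tab <- r$coefficients[r$coefficients$term != "(Intercept)", ]
        assoc_rows[[paste(oc, adj)]] <- cbind(
          outcome = oc, adjusted = adj, n = r$n, tab)
      }
    }
  }
  associations <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else NULL
  if (!is.null(associations)) {
    rownames(associations) <- NULL
    utils::write.csv(associations, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cosinorHRV")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    rows = list(metadata = nrow(cohort$metadata),
                segment_metrics = nrow(metrics_all),
                subjects = nrow(subjects),
                populations = length(pop_rows),
                comparisons = length(cmp_rows),
                associations = if (is.null(associations)) 0L
                               else nrow(associations)),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, metrics = metrics_list, fits = fits,
                 subjects = subjects, populations = populations,
                 comparisons = comparisons, associations = associations,
                 manifest = manifest))
}

# flatten a pipeline_config into plain lists for YAML round-tripping
serialize_config <- function(config) {
  list(seed = config$seed, duration_hours = config$duration_hours,
       min_segments = config$min_segments, period = config$period,
       groups = lapply(config$groups, function(g) {
         g <- unclass(g)
         g$covariates <- lapply(g$covariates, as.numeric)
         g
       }),
       artifacts = unclass(config$artifacts),
       preprocess = unclass(config$preprocess))
}
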