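#' End-to-end run configuration
#'
#' Bundles every setting of the full pipeline replay: cohort size and
#' seed, simulator settings, measurement criteria, fold count, the model
#' roster and feature sets. All randomness flows from the single master
#' seed; per-stage seeds are derived from it deterministically.
#'
#' @param seed Master seed.
#' @param n_patients Cohort size.
#' @param session [session_config()] settings.
#' @param dist [patient_distributions()] settings.
#' @param criteria [reduction_criteria()] settings.
#' @param k Number of patient-wise folds.
#' @param roster Character vector of model families to evaluate.
#' @param feature_sets Feature sets to evaluate for each model.
#' @param closed_loop Run the closed-loop stage with the best model.
#' @param control [controller_config()] for the closed-loop stage.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       n_patients = 20,
                       session = session_config(),
                       dist = patient_distributions(),
                       criteria = reduction_criteria(),
                       k = 3,
                       roster = c("logistic_regression", "random_forest",
                                  "svm", "neural_net", "lstm"),
                       feature_sets = c("gyro_only", "gyro_plus_prev"),
                       closed_loop = TRUE,
                       control = controller_config()) {
  structure(list(seed = seed, n_patients = n_patients, session = session,
                 dist = dist, criteria = criteria, k = k, roster = roster,
                 feature_sets = feature_sets, closed_loop = closed_loop,
                 control = control),
            class = "run_config")
}

# deterministic per-stage seeds fanned out from the master seed
stage_seed <- function(seed, stage) {
  (seed * 131L + match(stage, c("cohort", "session", "folds", "model",
                                "loop", "stats")) * 7919L) %% 2147483647L
}

#' Replay the full analysis pipeline on a synthetic cohort
#'
#' Runs every stage end to end: simulate a cohort of virtual patients and
#' their stimulation sessions, extract 1-s RMS features, compute
#' per-session reset summaries, build and filter labelled records, assign
#' patient-wise folds, cross-validate the model roster on both feature
#' sets, optionally run the closed-loop controller with the best model,
#' and compute the cohort statistics (before/during Wilcoxon tests and
#' the stepwise reset-time regression). Identical configs give identical
#' report bundles.
#'
#' @param config A [run_config()].
#' @return A `replay_report` list: `config`, `sessions` (per-patient
#'   reset summaries), `records`, `folds`, `fold_stats`, `models`
#'   (per-family, per-feature-set CV reports and improvement
#'   percentages), `closed_loop`, `stats`.
#' @export
replay <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$n_patients, stage_seed(config$seed, "cohort"),
                            config$dist)

  sessions <- list()
  all_records <- list()
  cohort_rows <- list()
  for (i in seq_along(cohort)) {
    prof <- cohort[[i]]
    stream <- simulate_session(prof, config$session,
                               seed = stage_seed(config$seed, "session") + i)
    windows <- rms_windows(stream)
    boundaries <- segment_session(windows)
    base <- baseline_rms(windows[boundaries$before, , drop = FALSE])
    summ <- compute_reset_summary(windows, boundaries, config$criteria, base)
    recs <- build_records(windows, prof$patient_id)
    reduced <- detect_reduction_state(windows, base, config$criteria)
    recs <- filter_records(recs, windows, reduced, boundaries,
                           config$criteria)$records
    sessions[[prof$patient_id]] <- summ
    all_records[[prof$patient_id]] <- recs
    before_w <- windows[boundaries$before, , drop = FALSE]
    during_w <- windows[boundaries$during, , drop = FALSE]
    cohort_rows[[i]] <- data.frame(
      patient_id = prof$patient_id,
      rms_x_before = mean(before_w$rms_x),
      rms_y_before = mean(before_w$rms_y),
      rms_z_before = mean(before_w$rms_z),
      rms_x_during = mean(during_w$rms_x),
      rms_y_during = mean(during_w$rms_y),
      rms_z_during = mean(during_w$rms_z),
      E = summ$avg_amplitude, A = summ$stim_duration_A,
      B = summ$reduction_during_B, C = summ$continuing_after_C,
      D = summ$reset_time_D,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  cohort_tab <- do.call(rbind, cohort_rows)

  folds <- grouped_folds(records$patient_id, k = config$k,
                         seed = stage_seed(config$seed, "folds"))
  fold_stats <- fold_summary(records, folds)

  models <- list()
  for (fam in config$roster) {
    fam_out <- list()
    for (fs in config$feature_sets) {
      spec <- model_spec(fam, feature_set = fs,
                         seed = stage_seed(config$seed, "model"))
      fam_out[[fs]] <- cross_validate(spec, records, folds)
    }
    if (all(c("gyro_only", "gyro_plus_prev") %in% names(fam_out))) {
      fam_out$improvement_pct <- c(
        macro_f1 = improvement_pct(
          unname(fam_out$gyro_only$mean["macro_f1"]),
          unname(fam_out$gyro_plus_prev$mean["macro_f1"])),
        accuracy = improvement_pct(
          unname(fam_out$gyro_only$mean["accuracy"]),
          unname(fam_out$gyro_plus_prev$mean["accuracy"])))
    }
    models[[fam]] <- fam_out
  }

  loop_out <- NULL
  if (isTRUE(config$closed_loop) && length(models)) {
    main_fs <- if ("gyro_plus_prev" %in% config$feature_sets) {
      "gyro_plus_prev"
    } else {
      config$feature_sets[1]
    }
    f1s <- vapply(models, function(m) {
      if (!is.null(m[[main_fs]])) m[[main_fs]]$mean["macro_f1"] else NA_real_
    }, numeric(1))
    best_fam <- names(models)[which.max(f1s)]
    best_spec <- model_spec(best_fam, feature_set = "gyro_plus_prev",
                            seed = stage_seed(config$seed, "model"))
    best_model <- fit_stim_model(best_spec, records)
    loop_res <- run_closed_loop(cohort[[1]], best_model, config$session,
                                config$control,
                                seed = stage_seed(config$seed, "loop"))
    loop_out <- list(best_family = best_fam, summary = loop_res$summary,
                     trace = loop_res$trace)
  }

  stats_out <- list(
    wilcoxon = list(
      rms_x = wilcoxon_signed_rank(cohort_tab$rms_x_before,
                                   cohort_tab$rms_x_during),
      rms_y = wilcoxon_signed_rank(cohort_tab$rms_y_before,
                                   cohort_tab$rms_y_during),
      rms_z = wilcoxon_signed_rank(cohort_tab$rms_z_before,
                                   cohort_tab$rms_z_during)),
    spearman_D_vs_E = spearman_rho(cohort_tab$D, cohort_tab$E),
    stepwise = stepwise_ols(cohort_tab, "D", c("E", "A")))

  structure(list(config = config, sessions = sessions, records = records,
                 cohort_table = cohort_tab, folds = folds,
                 fold_stats = fold_stats, models = models,
                 closed_loop = loop_out, stats = stats_out),
            class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  cat(sprintf("Pipeline replay: %d patients, %d records, %d-fold patient-wise CV\n",
              x$config$n_patients, nrow(x$records), x$config$k))
  for (fam in names(x$models)) {
    m <- x$models[[fam]]
    for (fs in intersect(names(m), c("gyro_only", "gyro_plus_prev"))) {
      cat(sprintf("  %-20s %-15s macro-F1 %.3f  accuracy %.3f\n", fam, fs,
                  m[[fs]]$mean["macro_f1"], m[[fs]]$mean["accuracy"]))
    }
  }
  if (!is.null(x$closed_loop)) {
    cat(sprintf("  closed loop (%s): reset time %.1f s\n",
                x$closed_loop$best_family,
                x$closed_loop$summary$reset_time_D))
  }
  invisible(x)
}

#' Write a replay report bundle to disk
#'
#' Emits the report as JSON (summary metrics, fold statistics, reset
#' summaries, statistics) plus CSV tables (records, cohort outcomes) in
#' the given directory.
#'
#' @param report A `replay_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_summ <- lapply(report$models, function(m) {
    out <- lapply(intersect(names(m), c("gyro_only", "gyro_plus_prev")),
                  function(fs) {
                    list(feature_set = fs,
                         per_fold = m[[fs]]$per_fold,
                         mean = as.list(m[[fs]]$mean),
                         sd = as.list(m[[fs]]$sd))
                  })
    if (!is.null(m$improvement_pct)) {
      out$improvement_pct <- as.list(m$improvement_pct)
    }
    out
  })
  bundle <- list(
    seed = report$config$seed,
    n_patients = report$config$n_patients,
    fold_counts = report$fold_stats$counts,
    fold_percentages = round(report$fold_stats$percentages, 2),
    sessions = lapply(report$sessions, function(s) {
      s$baseline_rms <- as.list(s$baseline_rms)
      unclass(s)
    }),
    models = model_summ,
    stats = list(
      wilcoxon = report$stats$wilcoxon,
      spearman_D_vs_E = report$stats$spearman_D_vs_E,
      stepwise = list(selected = report$stats$stepwise$selected,
                      coefficients = as.list(report$stats$stepwise$coefficients),
                      R = report$stats$stepwise$R,
                      R2 = report$stats$stepwise$R2))
  )
  if (!is.null(report$closed_loop)) {
    bundle$closed_loop <- list(
      best_family = report$closed_loop$best_family,
      summary = unclass(report$closed_loop$summary)[
        c("stim_duration_A", "reduction_during_B", "continuing_after_C",
          "reset_time_D", "max_amplitude", "avg_amplitude")]
    )
  }
  jsonlite::write_json(bundle, file.path(dir, "replay_report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cohort_table, file.path(dir, "cohort_outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
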