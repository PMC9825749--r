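#' Default pipeline configuration
#'
#' Nested list mirroring every module's documented options. Unknown keys in
#' a user config are rejected (typo protection) and the fully resolved
#' config is written next to every run's outputs.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42,
    input = list(features = NULL, metadata = NULL, time_unit = "months",
                 orientation = "samples_as_rows"),
    output_dir = "mbtraj_run",
    stages = list(explore = TRUE, transform = TRUE, trajectory = TRUE,
                  anomaly = TRUE, intervention = TRUE),
    synthetic = list(n_subjects = 40, samples_per_subject = 8,
                     n_features = 30, n_informative = 5,
                     time_range = c(0, 2), effect_size = 1, noise_sd = 0.3,
                     group_shift = 0, anomaly_frac = 0.05,
                     anomaly_magnitude = 8),
    exploration = list(n_bins = 10, embedding = "pca", n_dims = 2,
                       diversity = "shannon"),
    transform = list(pseudocount = NULL, n_bins = 10,
                     variance_quantile = 0.1, correlation_threshold = 0.99,
                     denominator_strategy = "crossings",
                     use_log_ratio = TRUE,
                     reference_mode = "declared", reference_group = NULL,
                     novelty_frac = 0.1),
    trajectory = list(regressor = "bagged_trees", level = 0.95,
                      interval = "prediction", cv_folds = 5,
                      leaderboard = c("linear", "ridge", "tree",
                                      "bagged_trees", "dummy")),
    anomaly = list(window = 5, k = 3, contamination = 0.05,
                   subsample_ratio = 1),
    intervention = list(k_max = 10, bandwidth = NULL, n_outliers = 3)
  )
}

# Merge a partial user config over the defaults, rejecting unknown keys.
resolve_config <- function(config = list()) {
  template <- default_config()
  check <- function(user, tmpl, path = character()) {
    if (!is.list(user)) return(invisible())
    bad <- setdiff(names(user), names(tmpl))
    if (length(bad) > 0) {
      stopf("unknown config key '%s'",
            paste(c(path, bad[1]), collapse = "."),
            class = c("mbtraj_config_error", "mbtraj_error"))
    }
    for (k in names(user)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        check(user[[k]], tmpl[[k]], c(path, k))
      }
    }
  }
  check(config, template)
  merge_lists <- function(tmpl, user) {
    for (k in names(user)) {
      tmpl[[k]] <- if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) &&
                       is.list(user[[k]])) {
        merge_lists(tmpl[[k]], user[[k]])
      } else {
        user[[k]]
      }
    }
    tmpl
  }
  merge_lists(template, config)
}

#' Run the full trajectory pipeline
#'
#' Executes the analysis stages in order — (a) exploration, (b) data
#' preparation, (c) trajectory construction, (d) outlier discovery,
#' (e) feature importance and intervention simulation — writing each
#' stage's CSV/JSON outputs, a plain-text log and the fully resolved
#' configuration to the output directory. Stages are individually
#' skippable via `stages`; a stage failure aborts with a stage-named
#' error. When no input paths are configured a synthetic demonstration
#' dataset is generated (with its ground truth) from the `synthetic`
#' config block.
#'
#' @param config partial configuration (nested list, or path to a YAML
#'   file) merged over [default_config()].
#' @return invisibly, a list with `output_dir` and the written file paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  log_path <- out("log.txt")
  cat("", file = log_path)
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  yaml::write_yaml(cfg, out("resolved_config.yaml"))
  written <- character()
  emit <- function(df, name) {
    readr::write_csv(tibble::as_tibble(df), out(name), progress = FALSE)
    written <<- c(written, out(name))
    logf("wrote %s", name)
  }
  stage <- function(name, code) {
    logf("stage %s: start", name)
    tryCatch(code, error = function(e) {
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      stopf("stage %s: %s", name, conditionMessage(e))
    })
  }
  logf("seed = %d", cfg$seed)

  # input: load or generate
  ds <- truth <- NULL
  stage("input", {
    if (is.null(cfg$input$features)) {
      sp <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = cfg$seed)))
      gen <- generate_dataset(sp)
      if (sp$anomaly_frac > 0) {
        gen <- inject_anomalies(gen$dataset, gen$truth, sp)
      }
      ds <- gen$dataset; truth <- gen$truth
      write_dataset(ds, cfg$output_dir)
      written <<- c(written, out("features.csv"), out("metadata.csv"))
      jsonlite::write_json(list(
        informative_features = truth$informative_features,
        anomalies = truth$anomalies), out("ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
      logf("generated synthetic dataset: %d samples", nrow(ds$features))
    } else {
      ds <- mb_dataset(
        read_feature_table(cfg$input$features,
                           orientation = cfg$input$orientation),
        read_sample_metadata(cfg$input$metadata),
        time_unit = cfg$input$time_unit)
      logf("loaded dataset: %d samples", nrow(ds$features))
    }
  })

  if (isTRUE(cfg$stages$explore)) stage("explore", {
    ss <- sampling_statistics(ds, n_bins = cfg$exploration$n_bins)
    emit(ss$per_subject, "sampling_per_subject.csv")
    emit(ss$per_timebin, "sampling_per_timebin.csv")
    feats <- ds$features
    if (value_kind(feats) == "logratio") feats <- NULL
    if (!is.null(feats)) {
      emit(alpha_diversity(feats, cfg$exploration$diversity),
           "alpha_diversity.csv")
    }
    emb <- embed_samples(ds, method = cfg$exploration$embedding,
                         n_dims = cfg$exploration$n_dims, seed = cfg$seed)
    emit(emb, "embedding.csv")
  })

  model_ds <- ds
  stage("transform", if (isTRUE(cfg$stages$transform)) {
    feats <- ds$features
    if (value_kind(feats) == "counts") feats <- to_relative_abundance(feats)
    feats <- filter_features(feats,
                             variance_quantile = cfg$transform$variance_quantile,
                             correlation_threshold = cfg$transform$correlation_threshold)
    emit(removal_log(feats), "feature_removal_log.csv")
    ds_f <- suppressWarnings(mb_dataset(feats, ds$metadata,
                                        time_unit = ds$time_unit))
    ref <- define_reference(ds_f, mode = cfg$transform$reference_mode,
                            reference_group = cfg$transform$reference_group,
                            novelty_frac = cfg$transform$novelty_frac,
                            seed = cfg$seed)
    emit(ref, "reference_assignment.csv")
    ds_f <- set_reference(ds_f, ref)
    if (isTRUE(cfg$transform$use_log_ratio)) {
      den <- select_denominator(ds_f,
                                strategy = cfg$transform$denominator_strategy,
                                n_bins = cfg$transform$n_bins,
                                pseudocount = cfg$transform$pseudocount,
                                seed = cfg$seed)
      emit(den$scores, "denominator_scores.csv")
      logf("denominator (%s): %s", den$strategy, den$feature_id)
      lr <- log_ratio_transform(ds_f$features, den$feature_id,
                                pseudocount = cfg$transform$pseudocount)
      ds_f <- suppressWarnings(mb_dataset(lr, ds_f$metadata,
                                          time_unit = ds$time_unit))
      ds_f$features <- set_value_kind(ds_f$features, "logratio")
    }
    model_ds <- ds_f
  })

  model <- mmi <- NULL
  if (isTRUE(cfg$stages$trajectory)) stage("trajectory", {
    model <- fit_mmi_model(model_ds, regressor = cfg$trajectory$regressor,
                            cv_folds = cfg$trajectory$cv_folds,
                            level = cfg$trajectory$level,
                            interval = cfg$trajectory$interval,
                            seed = cfg$seed)
    logf("MMI model grouped-CV R^2 = %.3f", model$cv_r2)
    mmi <- predict_mmi(model, model_ds)
    emit(mmi, "mmi_results.csv")
    lb <- compare_models(model_ds, regressors = cfg$trajectory$leaderboard,
                         cv_folds = cfg$trajectory$cv_folds, seed = cfg$seed)
    # fit_seconds is wall-clock noise; keep the emitted CSV reproducible
    emit(dplyr::select(tibble::as_tibble(lb), -"fit_seconds"),
         "leaderboard.csv")
  })

  reports <- list()
  if (isTRUE(cfg$stages$anomaly)) stage("anomaly", {
    if (is.null(mmi)) stopf("anomaly stage needs the trajectory stage")
    reports$interval <- interval_outliers(mmi)
    reports$lowpass <- lowpass_outliers(mmi, window = cfg$anomaly$window,
                                         k = cfg$anomaly$k)
    reports$isolation <- isolation_outliers(
      mmi, window = cfg$anomaly$window,
      contamination = cfg$anomaly$contamination, seed = cfg$seed)
    emit(dplyr::bind_rows(reports), "anomaly_report.csv")
    n_out <- sum(reports$interval$is_outlier)
    if (n_out >= 5 && sum(!reports$interval$is_outlier) >= 5) {
      expl <- explain_outliers(model_ds, reports$interval,
                               subsample_ratio = cfg$anomaly$subsample_ratio,
                               seed = cfg$seed)
      emit(expl$ranking, "outlier_explanation.csv")
      logf("outlier explanation AUROC = %.3f", expl$auroc)
    } else {
      logf("skipping outlier explanation (%d outliers)", n_out)
    }
  })

  if (isTRUE(cfg$stages$intervention)) stage("intervention", {
    if (is.null(model)) stopf("intervention stage needs the trajectory stage")
    out_ids <- reports$interval$sample_id[reports$interval$is_outlier]
    out_ids <- utils::head(out_ids, cfg$intervention$n_outliers)
    empty_report <- tibble::tibble(
      sample_id = character(), n_features_changed = integer(),
      features = character(), mmi_before = numeric(), mmi_after = numeric(),
      residual_before = numeric(), residual_after = numeric(),
      returned_to_interval = logical())
    if (length(out_ids) > 0) {
      res <- purrr::map_dfr(out_ids, function(sid) {
        iv <- simulate_intervention(model, model_ds, sid,
                                    k_max = cfg$intervention$k_max,
                                    bandwidth = cfg$intervention$bandwidth)
        tibble::tibble(sample_id = sid,
                       n_features_changed = nrow(iv$features_changed),
                       features = paste(iv$features_changed$feature_id,
                                        collapse = ";"),
                       mmi_before = iv$mmi_before, mmi_after = iv$mmi_after,
                       residual_before = iv$residual_before,
                       residual_after = iv$residual_after,
                       returned_to_interval = iv$returned_to_interval)
      })
      emit(res, "intervention_report.csv")
      if (length(out_ids) >= 2) {
        shared <- shared_outlier_features(model_ds, model, reports$interval,
                                          seed = cfg$seed)
        emit(shared, "shared_outlier_features.csv")
      }
    } else {
      emit(empty_report, "intervention_report.csv")
      logf("no interval outliers; empty intervention report written")
    }
  })

  logf("pipeline complete")
  invisible(list(output_dir = cfg$output_dir, files = written,
                 config = cfg))
}

#' @rdname run_pipeline
#' @param output_dir where the demo run writes its outputs.
#' @param seed master seed of the demo run.
#' @export
run_demo <- function(output_dir = tempfile("mbtraj_demo"), seed = 42) {
  run_pipeline(list(seed = seed, output_dir = output_dir))
}
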