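#' Ranked feature importance per user-defined time block
#'
#' Partitions time into half-open blocks `[e_i, e_{i+1})` from the given
#' edges and returns each block's features ranked by mean absolute Shapley
#' attribution (ties broken by feature id). Empty blocks warn and are
#' skipped.
#'
#' @param model an `mmi_model`.
#' @param ds an [mb_dataset()] (typically the reference samples).
#' @param block_edges increasing numeric vector of block boundaries.
#' @param ... passed to [feature_importance_over_time()].
#' @return tibble: block, t_lo, t_hi, feature_id, importance, rank.
#' @export
timeblock_importance <- function(model, ds, block_edges, ...) {
  if (length(block_edges) < 2 || any(diff(block_edges) <= 0)) {
    stopf("block_edges must be an increasing vector of >= 2 points")
  }
  windows <- purrr::map(seq_len(length(block_edges) - 1),
                        function(i) c(block_edges[i], block_edges[i + 1]))
  imp <- feature_importance_over_time(model, ds, windows, ...)
  imp |>
    dplyr::filter(!is.na(.data$importance)) |>
    dplyr::group_by(.data$window) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::rename(block = "window")
}

#' Time-local reference feature profile
#'
#' Median and IQR of each feature over reference samples within
#' `time +/- bandwidth`. When fewer than 5 reference samples fall in the
#' window the bandwidth doubles (up to 3 times) before giving up.
#'
#' @param ds an [mb_dataset()] (its reference samples are used).
#' @param time target time point.
#' @param bandwidth half-width of the time window; `NULL` defaults to a
#'   tenth of the observed time range.
#' @return tibble: feature_id, median, iqr; the bandwidth actually used is
#'   attribute `"bandwidth_used"`.
#' @export
reference_profile <- function(ds, time, bandwidth = NULL) {
  ref <- reference_subset(ds)
  bandwidth <- bandwidth %||% (diff(range(ref$metadata$time)) / 10)
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  bw <- bandwidth
  for (attempt in 0:3) {
    sel <- abs(ref$metadata$time - time) <= bw
    if (sum(sel) >= 5) break
    if (attempt == 3) {
      stopf("only %d reference samples within %.3g of time %.3g after widening",
            sum(sel), bw, time)
    }
    bw <- bw * 2
  }
  m <- feature_matrix(ref$features)[sel, , drop = FALSE]
  out <- tibble::tibble(feature_id = colnames(m),
                        median = unname(apply(m, 2, median)),
                        iqr = unname(apply(m, 2, stats::IQR)))
  attr(out, "bandwidth_used") <- bw
  out
}

#' Simulate an intervention returning a sample to the trajectory
#'
#' A model-space what-if: selected features of one sample are reset to the
#' time-local reference median ([reference_profile()]) and the MMI is
#' recomputed. Features can be given explicitly, or chosen per sample as
#' its top-attribution features, in which case k is escalated greedily
#' (1, 2, ...) until the sample returns inside the prediction interval (or
#' `k_max` is reached, reporting the best attempt). Unchanged features are
#' bit-identical between the before and after predictions; changing zero
#' features is a strict no-op. Post-intervention values are not
#' re-normalized to sum to 1: the model consumes the vector as-is (for
#' log-ratio inputs this is exact since they are scale-free; for relative
#' abundances it is a documented approximation).
#'
#' @param model an `mmi_model`.
#' @param ds an [mb_dataset()] containing the sample and the reference
#'   samples.
#' @param sample_id the sample to intervene on.
#' @param features explicit feature ids to reset (may be empty), or `NULL`
#'   to use `top_k` escalation.
#' @param top_k maximum number of top-attribution features (greedy mode).
#' @param k_max cap on the greedy escalation when `top_k` is `NULL`.
#' @param bandwidth passed to [reference_profile()].
#' @return class `mb_intervention`: sample_id, `features_changed` tibble
#'   (feature_id, old, new), mmi/residual before and after, and
#'   `returned_to_interval`.
#' @export
simulate_intervention <- function(model, ds, sample_id, features = NULL,
                                  top_k = NULL, k_max = 10, bandwidth = NULL) {
  stopifnot(inherits(model, "mmi_model"))
  if (!sample_id %in% ds$features$sample_id) {
    stopf("unknown sample '%s'", sample_id)
  }
  i <- match(sample_id, ds$features$sample_id)
  x <- feature_matrix(ds$features)[i, model$feature_ids_used, drop = FALSE]
  t_i <- ds$metadata$time[i]
  prof <- reference_profile(ds, t_i, bandwidth = bandwidth)
  target <- setNames(prof$median, prof$feature_id)
  expected <- curve_eval(model$curve, t_i)
  half <- interval_halfwidth(model$curve, t_i, kind = "prediction")
  mmi_before <- registry_predict(model$fit, x)
  residual_before <- mmi_before - expected
  apply_change <- function(feats) {
    x2 <- x
    if (length(feats) > 0) x2[1, feats] <- target[feats]
    mmi_after <- registry_predict(model$fit, x2)
    list(x2 = x2, mmi = mmi_after, resid = mmi_after - expected,
         inside = abs(mmi_after - expected) <= half)
  }
  if (!is.null(features)) {
    unknown <- setdiff(features, model$feature_ids_used)
    if (length(unknown) > 0) {
      stopf("unknown feature(s): %s", paste(unknown, collapse = ", "))
    }
    chosen <- features
    res <- apply_change(chosen)
  } else {
    k_cap <- top_k %||% k_max
    shap <- model_shapley(model, ds, sample_ids = sample_id)
    ranked <- colnames(shap$values)[order(-abs(shap$values[1, ]),
                                          colnames(shap$values))]
    res <- apply_change(character())
    chosen <- character()
    for (k in seq_len(min(k_cap, length(ranked)))) {
      cand <- ranked[seq_len(k)]
      trial <- apply_change(cand)
      chosen <- cand
      res <- trial
      if (trial$inside) break
    }
  }
  structure(list(sample_id = sample_id,
                 features_changed = tibble::tibble(
                   feature_id = chosen,
                   old = as.numeric(x[1, chosen]),
                   new = as.numeric(target[chosen])),
                 mmi_before = mmi_before, mmi_after = res$mmi,
                 residual_before = residual_before,
                 residual_after = res$resid,
                 returned_to_interval = res$inside,
                 time = t_i, expected_mmi = expected, halfwidth = half),
            class = "mb_intervention")
}

#' @export
print.mb_intervention <- function(x, ...) {
  cat(sprintf("<mb_intervention> sample '%s': %d feature(s) reset; residual %.3g -> %.3g; %s the %s interval\n",
              x$sample_id, nrow(x$features_changed), x$residual_before,
              x$residual_after,
              if (x$returned_to_interval) "inside" else "outside", "prediction"))
  invisible(x)
}

#' Features shared across detected outliers
#'
#' For every flagged outlier, its top-k features by per-sample absolute
#' Shapley attribution; the frequency with which each feature recurs across
#' outliers, contrasted with the same frequency over an equal-size seeded
#' draw of non-outlier samples.
#'
#' @param ds an [mb_dataset()].
#' @param model the `mmi_model` providing attributions.
#' @param report an `mb_anomaly_report` with >= 2 outliers.
#' @param top_k per-sample feature count.
#' @param seed integer seed for the contrast draw.
#' @return tibble: feature_id, outlier_freq, contrast_freq, sorted by
#'   descending outlier frequency.
#' @export
shared_outlier_features <- function(ds, model, report, top_k = 5, seed = 42) {
  stopifnot(inherits(report, "mb_anomaly_report"))
  idx <- match(ds$features$sample_id, report$sample_id)
  is_out <- report$is_outlier[idx]
  out_ids <- ds$features$sample_id[is_out]
  if (length(out_ids) < 2) stopf("need >= 2 outliers")
  non_ids <- ds$features$sample_id[!is_out]
  contrast_ids <- with_seed(child_seed(seed, 9), {
    sample(non_ids, min(length(out_ids), length(non_ids)))
  })
  top_feats <- function(ids) {
    shap <- model_shapley(model, ds, sample_ids = ids)
    apply(abs(shap$values), 1, function(v) {
      names(sort(v, decreasing = TRUE))[seq_len(min(top_k, length(v)))]
    }, simplify = FALSE)
  }
  freq_of <- function(tops, n) {
    tab <- table(unlist(tops)) / n
    tibble::tibble(feature_id = names(tab), freq = as.numeric(tab))
  }
  f_out <- freq_of(top_feats(out_ids), length(out_ids))
  f_con <- freq_of(top_feats(contrast_ids), length(contrast_ids))
  dplyr::full_join(dplyr::rename(f_out, outlier_freq = "freq"),
                   dplyr::rename(f_con, contrast_freq = "freq"),
                   by = "feature_id") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_freq"),
                                ~ tidyr::replace_na(.x, 0))) |>
    dplyr::arrange(dplyr::desc(.data$outlier_freq), .data$feature_id)
}
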