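new_anomaly_report <- function(mmi, method, score, is_outlier, parameters) {
  out <- tibble::tibble(sample_id = mmi$sample_id,
                        subject_id = mmi$subject_id,
                        time = mmi$time, method = method,
                        score = score, is_outlier = is_outlier)
  attr(out, "parameters") <- parameters
  class(out) <- c("mb_anomaly_report", class(out))
  out
}

#' Prediction-interval outliers
#'
#' Flags samples whose MMI falls outside the trajectory's prediction band;
#' the score is the absolute residual in local residual-SD units.
#'
#' @param mmi an `mmi_result` from [predict_mmi()] computed against a
#'   prediction (not confidence) band.
#' @param curve optional `trajectory_curve`; defaults to the one attached
#'   to `mmi`.
#' @return an `mb_anomaly_report` tibble: sample_id, subject_id, time,
#'   method, score, is_outlier.
#' @export
interval_outliers <- function(mmi, curve = NULL) {
  stopifnot(inherits(mmi, "mmi_result"))
  curve <- curve %||% attr(mmi, "curve")
  kind <- attr(mmi, "interval") %||% curve$interval_kind
  if (kind != "prediction") {
    stopf("interval outliers are defined against the prediction band")
  }
  scale <- pmax(residual_scale(curve, mmi$time, kind = "prediction"),
                .Machine$double.eps)
  new_anomaly_report(mmi, "interval",
                     score = abs(mmi$residual) / scale,
                     is_outlier = !mmi$within_interval,
                     parameters = list(level = attr(mmi, "level") %||% curve$level))
}

# Hampel-style deviation score. The reported low-pass signal is the rolling
# mean, but the score centres on the rolling median: a mean centre leaks an
# isolated spike into every overlapping window and would flag its innocent
# neighbours too. Scale is the rolling MAD x 1.4826 with a fallback chain
# for degenerate (locally constant) stretches: global MAD of deviations ->
# global mean |deviation| -> zero (when all deviations are 0).
lowpass_scores <- function(resid, window) {
  rmed <- rolling_stat(resid, window, median)
  dev <- resid - rmed
  rmad <- rolling_stat(resid, window, function(w) median(abs(w - median(w))))
  scale <- 1.4826 * rmad
  fb1 <- 1.4826 * median(abs(dev))
  fb2 <- mean(abs(dev))
  scale[scale == 0] <- if (fb1 > 0) fb1 else fb2
  ifelse(abs(dev) == 0, 0, ifelse(scale == 0, 0, abs(dev) / scale))
}

#' Low-pass (rolling-average) longitudinal outliers
#'
#' Sorts trajectory residuals by time and scores each sample by its
#' deviation from a centered rolling-window low-pass signal (window
#' shrinking at the edges) in robust units: the deviation is taken from the
#' rolling median and scaled by the rolling MAD times 1.4826, so that an
#' isolated spike is attributed to the spike alone rather than smeared over
#' its window neighbours. Slow drifts pass the filter; isolated spikes do
#' not. Series are processed per subject when every subject has at least
#' `window` samples, else globally.
#'
#' @param mmi an `mmi_result`.
#' @param window odd rolling-window width (>= 3).
#' @param k flagging threshold in robust SD units.
#' @return an `mb_anomaly_report` (method `"lowpass"`).
#' @export
lowpass_outliers <- function(mmi, window = 5, k = 3) {
  stopifnot(inherits(mmi, "mmi_result"))
  if (window < 3 || window %% 2 == 0) stopf("window must be odd and >= 3")
  if (nrow(mmi) < window) stopf("need at least %d samples", window)
  per_subject <- all(table(mmi$subject_id) >= window)
  score <- numeric(nrow(mmi))
  series <- if (per_subject) split(seq_len(nrow(mmi)), mmi$subject_id) else
    list(all = seq_len(nrow(mmi)))
  for (idx in series) {
    ord <- idx[order(mmi$time[idx])]
    score[ord] <- lowpass_scores(mmi$residual[ord], window)
  }
  new_anomaly_report(mmi, "lowpass", score = score, is_outlier = score > k,
                     parameters = list(window = window, k = k,
                                       per_subject = per_subject))
}

#' Isolation Forest longitudinal outliers
#'
#' Each sample is represented by its trajectory residual together with the
#' rolling mean and rolling SD of the time-sorted residual series; an
#' Isolation Forest scores these vectors and the top `contamination`
#' fraction (exactly `ceiling(contamination * n)` samples) is flagged.
#'
#' @param mmi an `mmi_result`.
#' @param window rolling-window width (>= 3).
#' @param contamination expected outlier fraction in (0, 0.5).
#' @param seed integer seed for the forest.
#' @return an `mb_anomaly_report` (method `"isolation"`).
#' @export
isolation_outliers <- function(mmi, window = 5, contamination = 0.05,
                               seed = 42) {
  stopifnot(inherits(mmi, "mmi_result"))
  if (window < 3) stopf("window must be >= 3")
  if (contamination <= 0 || contamination >= 0.5) {
    stopf("contamination must be in (0, 0.5)")
  }
  n <- nrow(mmi)
  ord <- order(mmi$time)
  r <- mmi$residual[ord]
  feats <- cbind(residual = r,
                 roll_mean = rolling_stat(r, window, mean),
                 roll_sd = rolling_stat(r, window,
                                        function(w) if (length(w) > 1) sd(w) else 0))
  forest <- isolation_forest(feats, seed = seed)
  sc <- isolation_score(forest, feats)
  score <- numeric(n); score[ord] <- sc
  n_flag <- ceiling(contamination * n)
  flagged <- order(-score, mmi$sample_id)[seq_len(n_flag)]
  new_anomaly_report(mmi, "isolation", score = score,
                     is_outlier = seq_len(n) %in% flagged,
                     parameters = list(window = window,
                                       contamination = contamination,
                                       seed = seed))
}

#' Explain detected outliers with a discriminating classifier
#'
#' Fits a gradient-boosted classifier separating the flagged outliers from
#' a (subsampled) background of the remaining samples, reports its
#' stratified cross-validated AUROC, and ranks features by mean absolute
#' Shapley attribution over the outlier samples. Optional metadata columns
#' enter one-hot encoded; `subject_id` and `time` are never allowed in
#' (leakage into the very trajectory being audited).
#'
#' @param ds an [mb_dataset()].
#' @param report an `mb_anomaly_report` over the same samples.
#' @param metadata_cols metadata columns to include as predictors.
#' @param subsample_ratio background size as a fraction of the non-outlier
#'   count, in (0, 1]; floored at the outlier count and capped at 3x it.
#' @param cv_folds stratified CV folds for the AUROC.
#' @param seed integer seed (subsample, folds).
#' @return class `mb_outlier_explanation`: classifier, auroc, `ranking`
#'   tibble (feature_id, importance), subsample_ratio, n_outliers,
#'   n_background.
#' @export
explain_outliers <- function(ds, report, metadata_cols = character(),
                             subsample_ratio = 1, cv_folds = 5, seed = 42) {
  stopifnot(inherits(report, "mb_anomaly_report"))
  if (subsample_ratio <= 0 || subsample_ratio > 1) {
    stopf("subsample_ratio must be in (0, 1]")
  }
  if (any(c("subject_id", "time", "sample_id") %in% metadata_cols)) {
    stopf("subject_id/time/sample_id must not be used as predictors")
  }
  idx <- match(ds$features$sample_id, report$sample_id)
  if (anyNA(idx)) stopf("report does not cover all dataset samples")
  is_out <- report$is_outlier[idx]
  n_out <- sum(is_out); n_non <- sum(!is_out)
  if (n_out < 5 || n_non < 5) {
    stopf("need >= 5 outliers and >= 5 non-outliers (got %d / %d)",
          n_out, n_non)
  }
  X <- feature_matrix(ds$features)
  for (col in metadata_cols) {
    if (!col %in% names(ds$metadata)) stopf("unknown metadata column '%s'", col)
    v <- ds$metadata[[col]]
    if (is.numeric(v)) {
      X <- cbind(X, setNames(data.frame(v), paste0("md_", col)))
      X <- as.matrix(X)
    } else {
      mm <- stats::model.matrix(~ f - 1, data.frame(f = factor(v)))
      colnames(mm) <- paste0("md_", col, "_", levels(factor(v)))
      X <- cbind(X, mm)
    }
  }
  n_bg <- max(n_out, min(round(subsample_ratio * n_non), 3 * n_out))
  n_bg <- min(n_bg, n_non)
  bg_rows <- with_seed(child_seed(seed, 3), sample(which(!is_out), n_bg))
  rows <- c(which(is_out), bg_rows)
  Xc <- X[rows, , drop = FALSE]
  y <- c(rep(1, n_out), rep(0, n_bg))
  if (length(unique(y)) < 2) stopf("degenerate classes")
  fit_clf <- function(Xtr, ytr) {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.2,
                    max_depth = 3, nthread = 1),
      data = xgboost::xgb.DMatrix(Xtr, label = ytr), nrounds = 60)
  }
  # stratified CV AUROC on out-of-fold probabilities
  folds <- integer(length(y))
  folds[y == 1] <- with_seed(child_seed(seed, 4),
                             sample(rep_len(seq_len(cv_folds), n_out)))
  folds[y == 0] <- with_seed(child_seed(seed, 5),
                             sample(rep_len(seq_len(cv_folds), n_bg)))
  fold_auc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      return(NA_real_)
    }
    m <- fit_clf(Xc[tr, , drop = FALSE], y[tr])
    pred <- stats::predict(m, xgboost::xgb.DMatrix(Xc[!tr, , drop = FALSE]))
    rank_auc(pred, y[!tr] == 1)
  }, numeric(1))
  auroc <- mean(fold_auc, na.rm = TRUE)
  clf <- fit_clf(Xc, y)
  bg_mat <- Xc[y == 0, , drop = FALSE]
  if (nrow(bg_mat) > 25) {
    bg_mat <- bg_mat[with_seed(child_seed(seed, 6),
                               sample(nrow(bg_mat), 25)), , drop = FALSE]
  }
  shap <- shapley_values(function(m) stats::predict(clf, xgboost::xgb.DMatrix(m)),
                         Xc[y == 1, , drop = FALSE], bg_mat,
                         n_perm = 8, seed = child_seed(seed, 8))
  imp <- colMeans(abs(shap$values))
  ranking <- tibble::tibble(feature_id = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature_id)
  structure(list(classifier = "boosted_trees", auroc = auroc,
                 ranking = ranking, subsample_ratio = subsample_ratio,
                 n_outliers = n_out, n_background = n_bg),
            class = "mb_outlier_explanation")
}

#' @export
print.mb_outlier_explanation <- function(x, ...) {
  cat(sprintf("<mb_outlier_explanation> %d outliers vs %d background, CV AUROC = %.3f; top feature: %s\n",
              x$n_outliers, x$n_background, x$auroc, x$ranking$feature_id[1]))
  invisible(x)
}
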