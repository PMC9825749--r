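#' Fit the smooth reference trajectory with interval bands
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized
#' cross-validation) of MMI against time, and estimates a time-varying
#' residual scale from binned mean absolute residuals (scaled by
#' \eqn{\sqrt{\pi/2}} to target the Gaussian SD, interpolated between bin
#' centers with a monotone shape-preserving Hermite spline so the scale
#' stays positive and overshoot-free, constant beyond the observed range).
#' The prediction band is `curve(t) +/- z * scale(t)`; the confidence band
#' divides the scale by the square root of the local bin count.
#'
#' @param times,mmis numeric vectors (>= 10 points).
#' @param level band level in (0.5, 1).
#' @param interval default band kind, `"prediction"` or `"confidence"`.
#' @param n_bins time bins for the residual-scale estimate.
#' @return class `trajectory_curve`. Evaluate with [curve_eval()],
#'   [residual_scale()] and [interval_halfwidth()].
#' @export
fit_trajectory_curve <- function(times, mmis, level = 0.95,
                                 interval = c("prediction", "confidence"),
                                 n_bins = 10) {
  interval <- match.arg(interval)
  if (length(times) < 10) stopf("trajectory fitting needs >= 10 points")
  if (level <= 0.5 || level >= 1) stopf("level must be in (0.5, 1)")
  if (length(unique(times)) < 4) stopf("need >= 4 distinct time points")
  ss <- gcv_spline(times, mmis, df_cap = 10)
  resid <- mmis - stats::predict(ss, times)$y
  bins <- time_bins(times, n_bins)
  idx <- bin_index(times, bins)
  used <- sort(unique(idx))
  centers <- (bins$lo[used] + bins$hi[used]) / 2
  scales <- vapply(used, function(b) {
    mean(abs(resid[idx == b])) * sqrt(pi / 2)
  }, numeric(1))
  counts <- vapply(used, function(b) sum(idx == b), numeric(1))
  structure(list(spline = ss, level = level, interval_kind = interval,
                 centers = centers, scales = scales, counts = counts,
                 time_range = range(times), n_points = length(times)),
            class = "trajectory_curve")
}

#' @rdname fit_trajectory_curve
#' @param curve a `trajectory_curve`.
#' @param t numeric vector of times.
#' @export
curve_eval <- function(curve, t) {
  stats::predict(curve$spline, as.numeric(t))$y
}

# Monotone (shape-preserving) interpolation of binned values, constant
# beyond the bin-center range.
interp_binned <- function(centers, values, t) {
  if (length(centers) == 1) return(rep(values, length(t)))
  f <- stats::splinefun(centers, values, method = "monoH.FC")
  pmax(0, f(pmin(pmax(t, min(centers)), max(centers))))
}

#' @rdname fit_trajectory_curve
#' @param kind band kind; defaults to the curve's own.
#' @export
residual_scale <- function(curve, t, kind = NULL) {
  kind <- kind %||% curve$interval_kind
  s <- interp_binned(curve$centers, curve$scales, t)
  if (kind == "confidence") {
    s <- s / sqrt(pmax(1, interp_binned(curve$centers, curve$counts, t)))
  }
  s
}

#' @rdname fit_trajectory_curve
#' @export
interval_halfwidth <- function(curve, t, kind = NULL, level = NULL) {
  level <- level %||% curve$level
  stats::qnorm((1 + level) / 2) * residual_scale(curve, t, kind)
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("<trajectory_curve> %d points, time %.3g-%.3g, %s band at %.0f%%\n",
              x$n_points, x$time_range[1], x$time_range[2], x$interval_kind,
              100 * x$level))
  invisible(x)
}

#' Fit the Microbiome Maturation Index model
#'
#' Trains a regressor to predict sample time ("microbiota age") from
#' feature abundances on the reference samples, then derives the smooth
#' reference trajectory from grouped-CV out-of-fold predictions of those
#' same training samples (out-of-fold rather than resubstitution, so that
#' the residual scale behind the interval bands is honest for flexible
#' models that interpolate their training data). Folds group by subject:
#' longitudinal repeats of one subject never straddle folds.
#'
#' @param ds an [mb_dataset()]; only samples flagged `is_reference` are
#'   used (all samples when the flag is absent).
#' @param regressor registry name, see [mb_regressors()].
#' @param features optional feature subset (ids) to train on.
#' @param cv_folds grouped CV folds for the out-of-fold trajectory.
#' @param level,interval default band settings stored on the curve.
#' @param seed integer seed (folds + stochastic fitters).
#' @return class `mmi_model`: regressor handle, `feature_ids_used`,
#'   `curve` ([fit_trajectory_curve()]), `training_samples`, `cv_r2`,
#'   `oof` tibble, and the seed. Methods: [predict_mmi()], `tidy()`,
#'   `glance()`, `autoplot()`.
#' @export
fit_mmi_model <- function(ds, regressor = "bagged_trees", features = NULL,
                          cv_folds = 5, level = 0.95,
                          interval = c("prediction", "confidence"),
                          seed = 42) {
  interval <- match.arg(interval)
  ref <- reference_subset(ds)
  if (nrow(ref$features) < 10) {
    stopf("MMI fitting needs >= 10 reference samples (got %d)",
          nrow(ref$features))
  }
  X <- feature_matrix(ref$features)
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss) > 0) stopf("unknown feature(s): %s",
                                paste(miss, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  y <- ref$metadata$time
  folds <- grouped_folds(ref$metadata$subject_id, k = cv_folds, seed = seed)
  oof <- numeric(length(y))
  r2s <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit_f <- registry_fit(regressor, X[tr, , drop = FALSE], y[tr],
                          seed = child_seed(seed, f))
    oof[!tr] <<- registry_predict(fit_f, X[!tr, , drop = FALSE])
    r_squared(y[!tr], oof[!tr])
  }, numeric(1))
  fit <- registry_fit(regressor, X, y, seed = seed)
  curve <- fit_trajectory_curve(y, oof, level = level, interval = interval)
  structure(list(fit = fit, regressor = regressor,
                 feature_ids_used = colnames(X),
                 train_X = X,
                 curve = curve,
                 training_samples = ref$features$sample_id,
                 oof = tibble::tibble(sample_id = ref$features$sample_id,
                                      subject_id = ref$metadata$subject_id,
                                      time = y, mmi_oof = oof, fold = folds),
                 cv_r2 = mean(r2s, na.rm = TRUE),
                 level = level, interval = interval, seed = seed),
            class = "mmi_model")
}

#' @export
print.mmi_model <- function(x, ...) {
  cat(sprintf("<mmi_model> regressor=%s, %d features, %d training samples, grouped-CV R^2 = %.3f\n",
              x$regressor, length(x$feature_ids_used),
              length(x$training_samples), x$cv_r2))
  invisible(x)
}

#' Predict the Microbiome Maturation Index
#'
#' Applies a fitted [fit_mmi_model()] to samples, returning each sample's
#' MMI (predicted time, in the dataset's time unit), its residual from the
#' reference trajectory at its actual time, and whether it falls inside the
#' requested interval band. Features beyond those the model uses are
#' ignored with a warning; missing required features are an error.
#'
#' @param model an `mmi_model`.
#' @param ds an [mb_dataset()].
#' @param interval,level band kind/level; default the model's.
#' @return tibble of class `mmi_result`: sample_id, subject_id, time,
#'   group, mmi, expected_mmi, residual, halfwidth, within_interval; the
#'   trajectory curve rides along as attribute `"curve"`.
#' @export
predict_mmi <- function(model, ds, interval = NULL, level = NULL) {
  stopifnot(inherits(model, "mmi_model"))
  interval <- interval %||% model$interval
  level <- level %||% model$level
  have <- feature_ids(ds$features)
  miss <- setdiff(model$feature_ids_used, have)
  if (length(miss) > 0) {
    stopf("dataset lacks required feature(s): %s", paste(miss, collapse = ", "))
  }
  extra <- setdiff(have, model$feature_ids_used)
  if (length(extra) > 0) {
    warnf("%d extra feature(s) ignored by the model", length(extra))
  }
  X <- feature_matrix(ds$features)[, model$feature_ids_used, drop = FALSE]
  mmi <- registry_predict(model$fit, X)
  t <- ds$metadata$time
  expected <- curve_eval(model$curve, t)
  half <- interval_halfwidth(model$curve, t, kind = interval, level = level)
  out <- tibble::tibble(sample_id = ds$metadata$sample_id,
                        subject_id = ds$metadata$subject_id,
                        time = t, group = ds$metadata$group,
                        mmi = mmi, expected_mmi = expected,
                        residual = mmi - expected,
                        halfwidth = half,
                        within_interval = abs(mmi - expected) <= half)
  attr(out, "curve") <- model$curve
  attr(out, "interval") <- interval
  attr(out, "level") <- level
  class(out) <- c("mmi_result", class(out))
  out
}

#' Feature importance over time windows
#'
#' Shapley attributions of the MMI regressor for every sample, averaged as
#' mean absolute attribution per feature within each time window. The
#' background distribution is a seeded draw of the model's training rows.
#'
#' @param model an `mmi_model`.
#' @param ds an [mb_dataset()] (typically the reference samples).
#' @param time_windows list of `c(lo, hi)` half-open windows `[lo, hi)`;
#'   the last window is closed on the right.
#' @param n_perm,n_background Shapley sampling effort.
#' @return tibble: window, t_lo, t_hi, n_samples, feature_id, importance
#'   (mean |attribution|; NA for empty windows, which also warn).
#' @export
feature_importance_over_time <- function(model, ds, time_windows,
                                         n_perm = 8, n_background = 25) {
  shap <- model_shapley(model, ds, n_perm = n_perm,
                        n_background = n_background)
  t <- ds$metadata$time
  hi_all <- max(vapply(time_windows, `[`, numeric(1), 2))
  purrr::imap_dfr(time_windows, function(w, wi) {
    sel <- t >= w[1] & (t < w[2] | (w[2] == hi_all & t == w[2]))
    if (!any(sel)) {
      warnf("time window [%g, %g) contains no samples", w[1], w[2])
      imp <- setNames(rep(NA_real_, ncol(shap$values)), colnames(shap$values))
    } else {
      imp <- colMeans(abs(shap$values[sel, , drop = FALSE]))
    }
    tibble::tibble(window = wi, t_lo = w[1], t_hi = w[2],
                   n_samples = sum(sel),
                   feature_id = names(imp), importance = unname(imp))
  })
}

# Shapley attributions of an mmi_model on a dataset's samples.
model_shapley <- function(model, ds, n_perm = 8, n_background = 25,
                          sample_ids = NULL) {
  X <- feature_matrix(ds$features)[, model$feature_ids_used, drop = FALSE]
  if (!is.null(sample_ids)) {
    X <- X[match(sample_ids, ds$features$sample_id), , drop = FALSE]
  }
  bg <- training_background(model, n_background)
  shapley_values(function(m) registry_predict(model$fit, m), X, bg,
                 n_perm = n_perm, seed = child_seed(model$seed, 7))
}

# Seeded draw of training rows used as the Shapley baseline distribution.
training_background <- function(model, n_background) {
  tr <- model$train_X
  if (nrow(tr) <= n_background) return(tr)
  keep <- with_seed(child_seed(model$seed, 11), sample(nrow(tr), n_background))
  tr[keep, , drop = FALSE]
}

#' Compare candidate regressors on grouped cross-validation
#'
#' Scores every requested registry regressor with identical grouped
#' (by-subject) folds and returns a leaderboard sorted by mean R-squared
#' (ties broken by model name). A model that fails to fit is recorded with
#' a failure flag and does not disturb the others.
#'
#' @param ds an [mb_dataset()] (reference samples are used).
#' @param regressors character vector of registry names (>= 2).
#' @param cv_folds number of grouped folds.
#' @param seed integer seed shared by all models.
#' @return tibble of class `mb_leaderboard`: model, mean_r2, sd_r2,
#'   mean_mae, fit_seconds, failed; fold fingerprint in attribute
#'   `"fold_hash"`.
#' @export
compare_models <- function(ds, regressors = mb_regressors()$name,
                           cv_folds = 5, seed = 42) {
  if (length(regressors) < 2) stopf("compare_models needs >= 2 models")
  ref <- reference_subset(ds)
  X <- feature_matrix(ref$features)
  y <- ref$metadata$time
  folds <- grouped_folds(ref$metadata$subject_id, k = cv_folds, seed = seed)
  rows <- purrr::map_dfr(regressors, function(m) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      per_fold <- purrr::map_dfr(sort(unique(folds)), function(f) {
        tr <- folds != f
        fit <- registry_fit(m, X[tr, , drop = FALSE], y[tr],
                            seed = child_seed(seed, f))
        pred <- registry_predict(fit, X[!tr, , drop = FALSE])
        tibble::tibble(r2 = r_squared(y[!tr], pred),
                       mae = mean(abs(y[!tr] - pred)))
      })
      tibble::tibble(model = m, mean_r2 = mean(per_fold$r2),
                     sd_r2 = sd(per_fold$r2), mean_mae = mean(per_fold$mae),
                     failed = FALSE)
    }, error = function(e) {
      tibble::tibble(model = m, mean_r2 = NA_real_, sd_r2 = NA_real_,
                     mean_mae = NA_real_, failed = TRUE)
    })
    res$fit_seconds <- proc.time()[["elapsed"]] - t0
    res
  })
  out <- dplyr::arrange(rows, dplyr::desc(!.data$failed),
                        dplyr::desc(.data$mean_r2), .data$model)
  attr(out, "fold_hash") <- fold_hash(folds)
  class(out) <- c("mb_leaderboard", class(out))
  out
}

#' Statistical comparison of two group trajectories
#'
#' Tests whether the MMI-versus-time trajectory differs between two groups.
#' `"linear"` fits `mmi ~ time + group + time:group` by least squares and
#' reports the F statistic for the joint null that both group terms are
#' zero. `"spline_permutation"` fits a smoothing spline per group,
#' takes the integrated squared difference between the two curves over
#' their common time range (201-point grid, trapezoidal rule), and builds
#' the null by permuting group labels at the subject level (all samples of
#' a subject swap together), stratified by each subject's median-time bin
#' so differing time densities are respected;
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @param ds an [mb_dataset()] containing both groups.
#' @param model a fitted `mmi_model` supplying the MMI.
#' @param group_a,group_b group labels (>= 10 samples each).
#' @param method `"linear"` or `"spline_permutation"`.
#' @param n_permutations permutation count (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return class `mb_trajectory_comparison`: method, statistic, p_value,
#'   per_group_fit, n_permutations, null_stats.
#' @export
compare_trajectories <- function(ds, model, group_a, group_b,
                                 method = c("linear", "spline_permutation"),
                                 n_permutations = 999, seed = 42) {
  method <- match.arg(method)
  md <- ds$metadata
  for (g in c(group_a, group_b)) {
    if (!g %in% md$group) {
      stopf("group '%s' not found; available labels: %s", g,
            paste(unique(md$group), collapse = ", "))
    }
  }
  sub <- dataset_subset(ds, md$sample_id[md$group %in% c(group_a, group_b)])
  res <- predict_mmi(model, sub)
  dat <- tibble::tibble(subject_id = res$subject_id, time = res$time,
                        group = res$group, mmi = res$mmi)
  compare_trajectories_mmi(dat, group_a, group_b, method = method,
                           n_permutations = n_permutations, seed = seed)
}

# Core comparison on a (subject_id, time, group, mmi) tibble.
compare_trajectories_mmi <- function(dat, group_a, group_b,
                                     method = c("linear", "spline_permutation"),
                                     n_permutations = 999, seed = 42) {
  method <- match.arg(method)
  na <- sum(dat$group == group_a); nb <- sum(dat$group == group_b)
  if (na < 10 || nb < 10) {
    stopf("both groups need >= 10 samples (got %d and %d)", na, nb)
  }
  ra <- range(dat$time[dat$group == group_a])
  rb <- range(dat$time[dat$group == group_b])
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (lo >= hi) stopf("groups have disjoint time ranges")
  if (method == "linear") {
    dat$group <- factor(dat$group, levels = c(group_a, group_b))
    full <- stats::lm(mmi ~ time * group, data = dat)
    reduced <- stats::lm(mmi ~ time, data = dat)
    an <- stats::anova(reduced, full)
    coefs <- stats::coef(full)
    per_group <- list()
    per_group[[group_a]] <- c(intercept = unname(coefs[1]),
                              slope = unname(coefs["time"]))
    per_group[[group_b]] <- c(
      intercept = unname(coefs[1] + coefs[3]),
      slope = unname(coefs["time"] + coefs[4]))
    out <- list(method = "linear", statistic = an$F[2],
                p_value = an$`Pr(>F)`[2], per_group_fit = per_group,
                n_permutations = 0L, null_stats = numeric())
  } else {
    if (n_permutations < 99) stopf("spline_permutation needs >= 99 permutations")
    grid <- seq(lo, hi, length.out = 201)
    stat_fun <- function(groups_of_subject) {
      g <- groups_of_subject[dat$subject_id]
      fa <- spline_on(dat$time[g == group_a], dat$mmi[g == group_a], grid)
      fb <- spline_on(dat$time[g == group_b], dat$mmi[g == group_b], grid)
      if (is.null(fa) || is.null(fb)) return(NA_real_)
      d2 <- (fa - fb)^2
      sum((d2[-1] + d2[-length(d2)]) / 2) * (hi - lo) / 200
    }
    subj_group <- tapply(dat$group, dat$subject_id, function(g) g[1])
    subj_group <- setNames(as.character(subj_group), names(subj_group))
    obs <- stat_fun(subj_group)
    if (is.na(obs)) stopf("cannot fit a per-group spline (too few distinct times)")
    subj_time <- tapply(dat$time, dat$subject_id, median)
    strata <- bin_index(subj_time, time_bins(subj_time, 4))
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        perm <- subj_group
        for (s in unique(strata)) {
          in_s <- strata == s
          perm[in_s] <- perm[in_s][sample(sum(in_s))]
        }
        stat_fun(perm)
      }, numeric(1))
    })
    ok <- !is.na(null_stats)
    p <- (1 + sum(null_stats[ok] >= obs)) / (1 + sum(ok))
    per_group <- list()
    per_group[[group_a]] <- spline_summary(dat, group_a, grid)
    per_group[[group_b]] <- spline_summary(dat, group_b, grid)
    out <- list(method = "spline_permutation", statistic = obs, p_value = p,
                per_group_fit = per_group, n_permutations = sum(ok),
                null_stats = null_stats[ok])
  }
  structure(out, class = "mb_trajectory_comparison")
}

# GCV-smoothed cubic spline with a degrees-of-freedom cap: GCV is known to
# pick near-interpolating lambdas on small samples with jittered ties, which
# would make permutation-null curves arbitrarily wiggly.
gcv_spline <- function(t, y, df_cap) {
  ss <- stats::smooth.spline(t, y, cv = FALSE)
  cap <- min(df_cap, length(unique(t)) - 1)
  # refit at the cap; smooth.spline may clamp to maximal smoothing with a
  # warning on near-degenerate subsets, which is the intended behaviour
  if (ss$df > cap) ss <- suppressWarnings(stats::smooth.spline(t, y, df = cap))
  ss
}

spline_on <- function(t, y, grid) {
  if (length(unique(t)) < 4) return(NULL)
  tryCatch({
    ss <- gcv_spline(t, y, df_cap = 6)
    stats::predict(ss, grid)$y
  }, error = function(e) NULL)
}

spline_summary <- function(dat, g, grid) {
  f <- spline_on(dat$time[dat$group == g], dat$mmi[dat$group == g], grid)
  tibble::tibble(time = grid, fitted_mmi = f)
}

#' @export
print.mb_trajectory_comparison <- function(x, ...) {
  cat(sprintf("<mb_trajectory_comparison> method=%s, statistic=%.4g, p=%.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (x$n_permutations > 0)
                sprintf(" (%d permutations)", x$n_permutations) else ""))
  invisible(x)
}
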