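#' Convert counts to relative abundances
#'
#' Divides each sample row by its total (closure). Rows with zero total are
#' an error: they carry no compositional information.
#'
#' @param features a feature table with `value_kind = "counts"`.
#' @return the closed table with `value_kind = "relative"`.
#' @export
to_relative_abundance <- function(features) {
  if (value_kind(features) == "logratio") {
    stopf("cannot close a log-ratio table to relative abundances")
  }
  m <- feature_matrix(features)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stopf("sample '%s' has zero total abundance", rownames(m)[which(tot <= 0)[1]])
  }
  out <- features
  out[feature_ids(features)] <- m / tot
  set_value_kind(out, "relative")
}

#' Remove low-variance and mutually correlated features
#'
#' Two deterministic passes: (1) features whose variance falls strictly
#' below the `variance_quantile` quantile of all feature variances are
#' dropped; (2) among the survivors, pairs with `|Pearson r| >=
#' correlation_threshold` are scanned in descending `|r|` (ties by feature
#' id) and the lower-variance member of each still-present pair is dropped.
#'
#' @param features a feature table with >= 2 features.
#' @param variance_quantile quantile in [0, 1) for the variance floor.
#' @param correlation_threshold absolute Pearson correlation in (0, 1]
#'   above which a pair is considered redundant. Relative-abundance tables
#'   are re-closed (rows renormalized to 1) after filtering; the retained
#'   subcomposition's log-ratios are unchanged by this.
#' @return the filtered table; the removal log (tibble: feature_id, reason,
#'   detail) is attached as attribute `"removal_log"`, see [removal_log()].
#' @export
filter_features <- function(features, variance_quantile = 0.1,
                            correlation_threshold = 0.99) {
  feats <- feature_ids(features)
  if (length(feats) < 2) stopf("filtering needs >= 2 features")
  if (variance_quantile < 0 || variance_quantile >= 1) {
    stopf("variance_quantile must be in [0, 1)")
  }
  m <- feature_matrix(features)
  vars <- apply(m, 2, var)
  floor_v <- unname(quantile(vars, variance_quantile))
  low <- feats[vars < floor_v]
  log_rows <- tibble::tibble(feature_id = low, reason = "low_variance",
                             detail = unname(vars[low]))
  keep <- setdiff(feats, low)
  if (length(keep) >= 2) {
    cm <- suppressWarnings(cor(m[, keep, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    pairs <- which(upper.tri(cm) & abs(cm) >= correlation_threshold,
                   arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      pr <- tibble::tibble(f1 = keep[pairs[, 1]], f2 = keep[pairs[, 2]],
                           r = cm[pairs])
      pr <- dplyr::arrange(pr, dplyr::desc(abs(.data$r)), .data$f1, .data$f2)
      removed <- character()
      for (i in seq_len(nrow(pr))) {
        f1 <- pr$f1[i]; f2 <- pr$f2[i]
        if (f1 %in% removed || f2 %in% removed) next
        victim <- if (vars[f1] <= vars[f2]) f1 else f2
        removed <- c(removed, victim)
        log_rows <- dplyr::bind_rows(log_rows, tibble::tibble(
          feature_id = victim, reason = "correlated", detail = pr$r[i]))
      }
      keep <- setdiff(keep, removed)
    }
  }
  if (length(keep) == 0) stopf("filtering would remove all features")
  kind <- value_kind(features)
  out <- features[c("sample_id", keep)]
  if (kind == "relative") {
    # re-close the retained subcomposition so rows still sum to 1
    sub <- as.matrix(out[keep])
    out[keep] <- sub / rowSums(sub)
  }
  out <- set_value_kind(out, kind)
  attr(out, "removal_log") <- log_rows
  out
}

#' @rdname filter_features
#' @export
removal_log <- function(features) {
  attr(features, "removal_log", exact = TRUE) %||%
    tibble::tibble(feature_id = character(), reason = character(),
                   detail = numeric())
}

# Default pseudocount: half the smallest non-zero value in the table.
default_pseudocount <- function(m) {
  nz <- m[m > 0]
  if (length(nz) == 0) stopf("table is all zeros")
  min(nz) / 2
}

#' Additive log-ratio transformation
#'
#' Replaces every abundance by `ln((v + pseudocount) / (v_D + pseudocount))`
#' where `v_D` is the chosen denominator feature's abundance in the same
#' sample; the denominator column is dropped. With `pseudocount = 0` on
#' strictly positive data the transform is scale-invariant per sample
#' (compositionally coherent).
#'
#' @param features a counts or relative feature table.
#' @param denominator feature id to place in the denominator.
#' @param pseudocount non-negative offset guarding zeros; `NULL` uses half
#'   the smallest non-zero value in the table.
#' @return the transformed table (`value_kind = "logratio"`), one column
#'   fewer; the denominator and pseudocount used are attached as attributes.
#' @export
log_ratio_transform <- function(features, denominator, pseudocount = NULL) {
  if (value_kind(features) == "logratio") {
    stopf("table is already log-ratio transformed")
  }
  feats <- feature_ids(features)
  if (!denominator %in% feats) {
    near <- feats[order(utils::adist(denominator, feats))]
    stopf("denominator '%s' not found; nearest feature ids: %s",
          denominator, paste(utils::head(near, 3), collapse = ", "))
  }
  m <- feature_matrix(features)
  pc <- pseudocount %||% default_pseudocount(m)
  if (pc < 0) stopf("pseudocount must be >= 0")
  if (pc == 0 && any(m == 0)) {
    stopf("pseudocount 0 requires strictly positive abundances")
  }
  lr <- log(m + pc) - log(m[, denominator] + pc)
  keep <- setdiff(feats, denominator)
  out <- features[c("sample_id", keep)]
  out[keep] <- lr[, keep, drop = FALSE]
  out <- set_value_kind(out, "logratio")
  attr(out, "denominator") <- denominator
  attr(out, "pseudocount") <- pc
  out
}

# Binned median trajectories (features x non-empty bins) on relative scale.
binned_median_matrix <- function(ds, n_bins) {
  feats <- ds$features
  if (value_kind(feats) == "counts") feats <- to_relative_abundance(feats)
  bins <- time_bins(ds$metadata$time, n_bins)
  idx <- bin_index(ds$metadata$time, bins)
  m <- feature_matrix(feats)
  used <- sort(unique(idx))
  med <- vapply(used, function(b) {
    apply(m[idx == b, , drop = FALSE], 2, median)
  }, numeric(ncol(m)))
  if (is.null(dim(med))) med <- matrix(med, nrow = ncol(m))
  rownames(med) <- colnames(m)
  med # features x non-empty bins, in time order
}

#' Trajectory crossings of a candidate denominator
#'
#' For the candidate feature, counts — summed over all other features — the
#' number of adjacent-time-bin sign changes of the difference between each
#' feature's binned median trajectory and the candidate's. Empty bins are
#' skipped; exact ties (zero difference) are compacted out before counting.
#' Fewer crossings indicate a temporally stable denominator.
#'
#' @param ds an [mb_dataset()].
#' @param candidate feature id.
#' @param n_bins number of time bins (>= 2).
#' @return a non-negative integer crossing count.
#' @export
count_crossings <- function(ds, candidate, n_bins = 10) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  feats <- feature_ids(ds$features)
  if (!candidate %in% feats) stopf("unknown feature '%s'", candidate)
  med <- binned_median_matrix(ds, n_bins)
  if (ncol(med) < 2) stopf("fewer than 2 non-empty time bins")
  crossings_against(med, candidate)
}

crossings_against <- function(med, candidate) {
  diffs <- sweep(med, 2, med[candidate, ]) # feature rows minus candidate
  diffs <- diffs[rownames(med) != candidate, , drop = FALSE]
  sum(apply(diffs, 1, function(s) {
    s <- sign(s)
    s <- s[s != 0]
    if (length(s) < 2) 0L else sum(s[-1] != s[-length(s)])
  }))
}

#' Differential ranking of features against time
#'
#' Spearman rank correlation between each feature's relative abundance and
#' sample time — a monotone time-association score in [-1, 1]. Constant
#' features score 0. Extremely low or high scores identify candidate
#' log-ratio denominators with strong monotone behaviour.
#'
#' @param ds an [mb_dataset()] with >= 3 distinct time points.
#' @return tibble: feature_id, ranking.
#' @export
differential_ranking <- function(ds) {
  if (length(unique(ds$metadata$time)) < 3) {
    stopf("differential ranking needs >= 3 distinct time points")
  }
  feats <- ds$features
  if (value_kind(feats) == "counts") feats <- to_relative_abundance(feats)
  m <- feature_matrix(feats)
  rho <- suppressWarnings(
    apply(m, 2, function(v) cor(v, ds$metadata$time, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  tibble::tibble(feature_id = colnames(m), ranking = unname(rho))
}

#' Select the log-ratio denominator feature
#'
#' Four strategies: `"crossings"` minimizes the trajectory crossing count
#' ([count_crossings()]); `"ranking_low"` / `"ranking_high"` take the
#' extreme of the Spearman-versus-time [differential_ranking()];
#' `"performance"` log-ratio-transforms the reference samples with each
#' candidate denominator in turn, fits the MMI regressor under grouped
#' (by-subject) cross-validation and picks the candidate maximizing mean
#' R-squared. Ties are broken lexicographically by feature id.
#'
#' @param ds an [mb_dataset()].
#' @param strategy one of crossings, ranking_low, ranking_high, performance.
#' @param model regressor registry name (performance strategy).
#' @param cv_folds grouped CV folds (performance strategy).
#' @param n_bins time bins for the crossings strategy.
#' @param pseudocount passed to [log_ratio_transform()].
#' @param seed integer seed for CV fold assignment and stochastic models.
#' @return class `mb_denominator_report`: list with `feature_id` (the
#'   choice), `strategy`, `scores` tibble (feature_id, score) and
#'   `ties_broken` flag. `tidy()` returns the scores.
#' @export
select_denominator <- function(ds, strategy = c("crossings", "ranking_low",
                                                "ranking_high", "performance"),
                               model = "bagged_trees", cv_folds = 5,
                               n_bins = 10, pseudocount = NULL, seed = 42) {
  strategy <- match.arg(strategy)
  feats <- feature_ids(ds$features)
  if (length(feats) < 2) stopf("denominator selection needs >= 2 features")
  scores <- switch(strategy,
    crossings = {
      med <- binned_median_matrix(ds, n_bins)
      if (ncol(med) < 2) stopf("fewer than 2 non-empty time bins")
      vapply(feats, function(f) as.numeric(crossings_against(med, f)),
             numeric(1))
    },
    ranking_low = ,
    ranking_high = {
      dr <- differential_ranking(ds)
      setNames(dr$ranking, dr$feature_id)
    },
    performance = {
      if (is.null(model)) stopf("performance strategy needs a model name")
      ref <- reference_subset(ds)
      vapply(feats, function(f) {
        lr <- log_ratio_transform(ref$features, f, pseudocount = pseudocount)
        cv_mean_r2(feature_matrix(lr), ref$metadata$time,
                   ref$metadata$subject_id, model, cv_folds, seed)
      }, numeric(1))
    })
  pick_best <- function(s, maximize) {
    best <- if (maximize) max(s) else min(s)
    winners <- sort(names(s)[s == best])
    list(id = winners[1], tie = length(winners) > 1)
  }
  maximize <- strategy %in% c("ranking_high", "performance")
  best <- pick_best(scores, maximize)
  structure(list(feature_id = best$id, strategy = strategy,
                 scores = tibble::tibble(feature_id = names(scores),
                                         score = unname(scores)),
                 ties_broken = best$tie),
            class = "mb_denominator_report")
}

#' @export
print.mb_denominator_report <- function(x, ...) {
  cat(sprintf("<mb_denominator_report> strategy=%s, chosen='%s'%s\n",
              x$strategy, x$feature_id,
              if (x$ties_broken) " (tie broken lexicographically)" else ""))
  invisible(x)
}

# Grouped-CV mean R^2 of a registry regressor predicting y from X.
cv_mean_r2 <- function(X, y, groups, model, cv_folds, seed) {
  folds <- grouped_folds(groups, k = cv_folds, seed = seed)
  mean(vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- registry_fit(model, X[tr, , drop = FALSE], y[tr],
                        seed = child_seed(seed, f))
    r2 <- r_squared(y[!tr], registry_predict(fit, X[!tr, , drop = FALSE]))
    if (is.na(r2)) 0 else r2
  }, numeric(1)))
}

#' Build a hybrid feature set
#'
#' Union of the top-k model-important features and analyst-supplied domain
#' features: importance order first, domain additions in their given order,
#' duplicates removed.
#'
#' @param importances named numeric vector or tibble (feature_id,
#'   importance) of model importances.
#' @param top_k how many model features to keep (>= 1).
#' @param domain_features character vector of ids to force-include; ids
#'   absent from the importance map are an error.
#' @return ordered character vector of feature ids.
#' @export
build_hybrid_feature_set <- function(importances, top_k,
                                     domain_features = character()) {
  if (is.data.frame(importances)) {
    importances <- setNames(importances$importance, importances$feature_id)
  }
  if (top_k < 1) stopf("top_k must be >= 1")
  unknown <- setdiff(domain_features, names(importances))
  if (length(unknown) > 0) {
    stopf("unknown domain feature id(s): %s", paste(unknown, collapse = ", "))
  }
  ord <- names(sort(importances, decreasing = TRUE))
  top <- utils::head(ord, top_k)
  unique(c(top, domain_features))
}

#' Define the reference sample set
#'
#' The reference group anchors the trajectory. Three modes: `"declared"`
#' passes through existing `is_reference` flags; `"group_label"` flags the
#' samples of one group; `"novelty"` fits an isolation-based one-class
#' boundary on the declared/group seed set, re-admits non-seed samples
#' whose novelty score lies within the seed set's score range, and expels
#' the most extreme `novelty_frac` tail of the seed set itself.
#'
#' @param ds an [mb_dataset()].
#' @param mode `"declared"`, `"group_label"` or `"novelty"`.
#' @param reference_group group label (group_label mode, and the seed set
#'   of novelty mode when `is_reference` is absent).
#' @param novelty_frac fraction of the seed set to expel, in (0, 0.5].
#' @param seed integer seed for the isolation forest.
#' @return class `mb_reference`: tibble (sample_id, is_reference,
#'   novelty_score) with attribute `mode`. Fewer than 10 reference samples
#'   is an error (trajectory fitting needs mass). Apply with
#'   [set_reference()].
#' @export
define_reference <- function(ds, mode = c("declared", "group_label", "novelty"),
                             reference_group = NULL, novelty_frac = 0.1,
                             seed = 42) {
  mode <- match.arg(mode)
  md <- ds$metadata
  seed_flags <- function() {
    if ("is_reference" %in% names(md) && !all(is.na(md$is_reference))) {
      !is.na(md$is_reference) & md$is_reference
    } else if (!is.null(reference_group)) {
      md$group == reference_group
    } else {
      stopf("novelty mode needs declared is_reference flags or a reference_group")
    }
  }
  out <- switch(mode,
    declared = {
      if (!"is_reference" %in% names(md)) {
        stopf("mode 'declared' requires an is_reference metadata column")
      }
      tibble::tibble(sample_id = md$sample_id,
                     is_reference = !is.na(md$is_reference) & md$is_reference,
                     novelty_score = NA_real_)
    },
    group_label = {
      if (is.null(reference_group)) stopf("mode 'group_label' needs reference_group")
      if (!reference_group %in% md$group) {
        stopf("group '%s' not found; available labels: %s", reference_group,
              paste(unique(md$group), collapse = ", "))
      }
      tibble::tibble(sample_id = md$sample_id,
                     is_reference = md$group == reference_group,
                     novelty_score = NA_real_)
    },
    novelty = {
      if (novelty_frac <= 0 || novelty_frac > 0.5) {
        stopf("novelty_frac must be in (0, 0.5]")
      }
      sd_idx <- seed_flags()
      if (sum(sd_idx) < 10) stopf("novelty mode needs >= 10 seed samples")
      m <- feature_matrix(ds$features)
      forest <- isolation_forest(m[sd_idx, , drop = FALSE], seed = seed)
      score <- isolation_score(forest, m)
      seed_scores <- score[sd_idx]
      cutoff <- unname(quantile(seed_scores, 1 - novelty_frac))
      keep_seed <- sd_idx & score <= cutoff
      admit <- !sd_idx & score >= min(seed_scores) & score <= max(seed_scores)
      tibble::tibble(sample_id = md$sample_id,
                     is_reference = keep_seed | admit,
                     novelty_score = score)
    })
  if (sum(out$is_reference) < 10) {
    stopf("only %d reference samples after assignment; need >= 10",
          sum(out$is_reference))
  }
  attr(out, "mode") <- mode
  class(out) <- c("mb_reference", class(out))
  out
}

#' @rdname define_reference
#' @param assignment an `mb_reference` from [define_reference()].
#' @export
set_reference <- function(ds, assignment) {
  stopifnot(inherits(assignment, "mb_reference"))
  idx <- match(ds$metadata$sample_id, assignment$sample_id)
  if (anyNA(idx)) stopf("assignment does not cover all dataset samples")
  ds$metadata$is_reference <- assignment$is_reference[idx]
  ds
}
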