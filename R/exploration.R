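#' Sampling statistics for a longitudinal dataset
#'
#' Summarizes study design density: samples per subject and samples per
#' time bin. Bins partition the observed time axis into `n_bins` equal-width
#' half-open intervals `[lo, hi)`, the final bin closed on the right, so
#' every sample falls in exactly one bin.
#'
#' @param ds an [mb_dataset()].
#' @param n_bins number of equal-width time bins (>= 1).
#' @return an object of class `mb_sampling_summary`: list with tibbles
#'   `per_subject` (subject_id, n_samples) and `per_timebin`
#'   (bin, t_lo, t_hi, n_samples).
#' @export
sampling_statistics <- function(ds, n_bins = 10) {
  if (n_bins < 1) stopf("n_bins must be >= 1")
  md <- ds$metadata
  per_subject <- dplyr::count(md, .data$subject_id, name = "n_samples")
  bins <- time_bins(md$time, n_bins)
  idx <- bin_index(md$time, bins)
  per_timebin <- tibble::tibble(bin = seq_len(n_bins),
                                t_lo = bins$lo, t_hi = bins$hi) |>
    dplyr::left_join(tibble::tibble(bin = idx) |>
                       dplyr::count(.data$bin, name = "n_samples"),
                     by = "bin") |>
    dplyr::mutate(n_samples = tidyr::replace_na(.data$n_samples, 0L))
  structure(list(per_subject = per_subject, per_timebin = per_timebin,
                 time_unit = ds$time_unit),
            class = "mb_sampling_summary")
}

#' @export
print.mb_sampling_summary <- function(x, ...) {
  cat(sprintf("<mb_sampling_summary> %d subjects, %d samples in %d time bins (%s)\n",
              nrow(x$per_subject), sum(x$per_subject$n_samples),
              nrow(x$per_timebin), x$time_unit))
  invisible(x)
}

# Equal-width half-open bins over the observed range; final bin closed.
time_bins <- function(times, n_bins) {
  lo <- min(times); hi <- max(times)
  if (hi == lo) hi <- lo + 1 # degenerate range: single catch-all width
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  list(lo = breaks[-length(breaks)], hi = breaks[-1], breaks = breaks)
}

bin_index <- function(times, bins) {
  pmin(findInterval(times, bins$breaks, rightmost.closed = TRUE),
       length(bins$lo))
}

#' Per-time-bin feature summaries
#'
#' Median (or mean) relative abundance of every feature per time bin —
#' the numeric backbone of dense abundance-over-time displays.
#'
#' @inheritParams sampling_statistics
#' @param stat `"median"` or `"mean"`.
#' @return tibble: bin, t_lo, t_hi, n_samples, then one column per feature.
#' @export
binned_abundance <- function(ds, n_bins = 10, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  bins <- time_bins(ds$metadata$time, n_bins)
  idx <- bin_index(ds$metadata$time, bins)
  m <- feature_matrix(ds$features)
  rows <- purrr::map_dfr(seq_len(n_bins), function(b) {
    sel <- idx == b
    vals <- if (any(sel)) apply(m[sel, , drop = FALSE], 2, f) else
      setNames(rep(NA_real_, ncol(m)), colnames(m))
    dplyr::bind_cols(tibble::tibble(bin = b, t_lo = bins$lo[b],
                                    t_hi = bins$hi[b], n_samples = sum(sel)),
                     tibble::as_tibble(as.list(vals)))
  })
  rows
}

#' Alpha diversity per sample
#'
#' Shannon entropy (natural log) or the Gini-Simpson index, computed on
#' per-sample proportions. Log-ratio tables are rejected: diversity is
#' undefined on signed data.
#'
#' @param features a feature table with `value_kind` counts or relative.
#' @param index `"shannon"` (\eqn{-\sum p_i \ln p_i}) or `"simpson"`
#'   (\eqn{1 - \sum p_i^2}).
#' @return tibble with columns sample_id and diversity, in table order.
#' @export
alpha_diversity <- function(features, index = c("shannon", "simpson")) {
  index <- match.arg(index)
  if (value_kind(features) == "logratio") {
    stopf("alpha diversity is undefined for log-ratio tables")
  }
  m <- feature_matrix(features)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stopf("sample '%s' has non-positive total abundance",
          rownames(m)[which(tot <= 0)[1]])
  }
  div <- vegan::diversity(m, index = if (index == "shannon") "shannon" else "simpson")
  tibble::tibble(sample_id = features$sample_id, diversity = unname(div))
}

#' Rank-based two-group differential feature test
#'
#' Per feature, a two-sided Mann-Whitney (Wilcoxon rank-sum) test of group A
#' versus group B abundances (exact when sample sizes permit and no ties,
#' else normal approximation with tie correction), with Benjamini-Hochberg
#' q-values across features and the direction of the group-A-minus-group-B
#' median difference.
#'
#' @param ds an [mb_dataset()].
#' @param group_a,group_b group labels present in the metadata.
#' @return tibble: feature_id, statistic (Mann-Whitney U for group A),
#'   p_value, q_value, direction (-1/0/+1).
#' @export
two_group_feature_test <- function(ds, group_a, group_b) {
  md <- ds$metadata
  avail <- unique(md$group)
  for (g in c(group_a, group_b)) {
    if (!g %in% avail) {
      stopf("group '%s' not found; available labels: %s",
            g, paste(avail, collapse = ", "))
    }
  }
  a_idx <- md$group == group_a
  b_idx <- md$group == group_b
  if (sum(a_idx) < 3 || sum(b_idx) < 3) {
    stopf("both groups need >= 3 samples (got %d and %d)",
          sum(a_idx), sum(b_idx))
  }
  m <- feature_matrix(ds$features)
  res <- purrr::map_dfr(colnames(m), function(f) {
    x <- m[a_idx, f]; y <- m[b_idx, f]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      return(tibble::tibble(feature_id = f,
                            statistic = length(x) * length(y) / 2,
                            p_value = 1, direction = 0))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    tibble::tibble(feature_id = f, statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   direction = sign(median(x) - median(y)))
  })
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::relocate(res, "feature_id", "statistic", "p_value", "q_value",
                  "direction")
}
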