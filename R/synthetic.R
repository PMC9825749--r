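#' Specification for a synthetic longitudinal microbiome dataset
#'
#' The generator draws per-feature log-abundances and closes them to
#' relative abundances, emulating a longitudinal design of repeatedly
#' sampled subjects (compositional counts, a known set of time-informative
#' taxa, optionally a second group whose maturation is shifted in time, and
#' optionally planted single-feature anomalies).
#'
#' Informative feature `j` has log-abundance `b_j * effect_size * t +
#' N(0, noise_sd)` with signs `b_j` alternating +1/-1 so that both
#' increasing and decreasing taxa exist; the remaining features are
#' `N(0, noise_sd)`. Subjects are sampled at equally spaced times with
#' +/-5% jitter of the spacing.
#'
#' @param n_subjects,samples_per_subject,n_features,n_informative design sizes.
#' @param time_range numeric length-2, observation window (time units).
#' @param effect_size per-unit-time slope of informative log-abundance.
#' @param noise_sd log-scale noise standard deviation.
#' @param group_shift time offset applied to the informative means of the
#'   second ("treatment") group; 0 means a single group.
#' @param anomaly_frac fraction of samples to corrupt in [inject_anomalies()].
#' @param anomaly_magnitude anomaly size in units of `noise_sd` (log scale).
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 40, samples_per_subject = 8,
                           n_features = 30, n_informative = 5,
                           time_range = c(0, 2), effect_size = 1,
                           noise_sd = 0.3, group_shift = 0,
                           anomaly_frac = 0, anomaly_magnitude = 8,
                           seed = 42) {
  spec <- list(n_subjects = n_subjects,
               samples_per_subject = samples_per_subject,
               n_features = n_features, n_informative = n_informative,
               time_range = as.numeric(time_range),
               effect_size = effect_size, noise_sd = noise_sd,
               group_shift = group_shift, anomaly_frac = anomaly_frac,
               anomaly_magnitude = anomaly_magnitude, seed = seed)
  if (spec$n_informative > spec$n_features) {
    stopf("n_informative (%d) exceeds n_features (%d)",
          spec$n_informative, spec$n_features)
  }
  if (spec$n_subjects < 1 || spec$samples_per_subject < 1 || spec$n_features < 1) {
    stopf("all design counts must be >= 1")
  }
  if (spec$anomaly_frac < 0 || spec$anomaly_frac >= 0.5) {
    stopf("anomaly_frac must be in [0, 0.5)")
  }
  if (length(spec$time_range) != 2 || diff(spec$time_range) <= 0) {
    stopf("time_range must be an increasing pair")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `dataset` (an [mb_dataset()] of relative abundances;
#'   when `group_shift != 0` half the subjects form a "treatment" group and
#'   only "control" samples are flagged as reference) and `truth`, a list
#'   holding `informative_features`, a `samples` tibble (sample_id,
#'   true_time, group) and an `anomalies` tibble (empty until
#'   [inject_anomalies()]).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects * spec$samples_per_subject
  p <- spec$n_features
  signs <- rep_len(c(1, -1), spec$n_informative)
  feat_ids <- sprintf("taxon_%02d", seq_len(p))
  informative <- feat_ids[seq_len(spec$n_informative)]

  res <- with_seed(spec$seed, {
    subj <- sprintf("subject_%02d", seq_len(spec$n_subjects))
    two_groups <- spec$group_shift != 0
    grp_of <- if (two_groups) {
      rep(c("control", "treatment"), length.out = spec$n_subjects)
    } else {
      rep("control", spec$n_subjects)
    }
    spacing <- diff(spec$time_range) / max(1, spec$samples_per_subject - 1)
    md <- purrr::map_dfr(seq_len(spec$n_subjects), function(i) {
      base <- seq(spec$time_range[1], spec$time_range[2],
                  length.out = spec$samples_per_subject)
      t <- pmax(0, base + stats::runif(spec$samples_per_subject,
                                       -0.05, 0.05) * spacing)
      tibble::tibble(sample_id = sprintf("%s_t%02d", subj[i],
                                         seq_len(spec$samples_per_subject)),
                     subject_id = subj[i], time = t, group = grp_of[i])
    })
    t_eff <- md$time + ifelse(md$group == "treatment", spec$group_shift, 0)
    logab <- matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    for (j in seq_len(spec$n_informative)) {
      logab[, j] <- logab[, j] + signs[j] * spec$effect_size * t_eff
    }
    list(md = md, logab = logab)
  })
  ab <- exp(res$logab)
  rel <- ab / rowSums(ab)
  colnames(rel) <- feat_ids
  rownames(rel) <- res$md$sample_id
  md <- res$md
  md$is_reference <- md$group == "control"
  ds <- suppressWarnings(
    mb_dataset(feature_table(rel, value_kind = "relative"), md,
               time_unit = "months"))
  truth <- list(
    informative_features = informative,
    feature_signs = setNames(signs, informative),
    samples = tibble::tibble(sample_id = md$sample_id, true_time = md$time,
                             group = md$group),
    anomalies = tibble::tibble(sample_id = character(), feature_id = character())
  )
  list(dataset = ds, truth = truth)
}

#' Plant single-feature anomalies in a generated dataset
#'
#' A seeded `anomaly_frac` of samples have one informative feature's
#' log-abundance shifted by `anomaly_magnitude * noise_sd` before the row is
#' re-closed to sum to 1; the affected sample/feature pairs are appended to
#' the ground truth.
#'
#' @param ds the dataset from [generate_dataset()].
#' @param truth its ground-truth list.
#' @param spec the originating [synthetic_spec()] (carries fraction,
#'   magnitude, noise level and seed).
#' @return list with the corrupted `dataset` and updated `truth`.
#' @export
inject_anomalies <- function(ds, truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$anomaly_frac <= 0) stopf("anomaly_frac must be > 0 to inject")
  n <- nrow(ds$features)
  n_anom <- round(spec$anomaly_frac * n)
  picks <- with_seed(child_seed(spec$seed, 101), {
    idx <- sample(n, n_anom)
    feats <- sample(truth$informative_features, n_anom, replace = TRUE)
    list(idx = idx, feats = feats)
  })
  m <- feature_matrix(ds$features)
  factor <- exp(spec$anomaly_magnitude * spec$noise_sd)
  for (k in seq_len(n_anom)) {
    i <- picks$idx[k]
    m[i, picks$feats[k]] <- m[i, picks$feats[k]] * factor
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  out <- ds
  out$features <- feature_table(m, value_kind = "relative")
  out$features <- out$features[match(ds$features$sample_id,
                                     out$features$sample_id), ]
  out$features <- set_value_kind(out$features, "relative")
  truth$anomalies <- tibble::tibble(
    sample_id = ds$features$sample_id[picks$idx],
    feature_id = picks$feats)
  list(dataset = out, truth = truth)
}
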