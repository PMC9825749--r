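# Shared fixtures, all generated in code at test time.

# Small longitudinal dataset from an explicit matrix.
tiny_dataset <- function(m, times = NULL, subjects = NULL, groups = NULL,
                         value_kind = "counts") {
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  md <- tibble::tibble(
    sample_id = rownames(m),
    subject_id = subjects %||% rownames(m),
    time = times %||% rep(seq_len(ceiling(n / 2)), length.out = n),
    group = groups %||% "all")
  suppressWarnings(mb_dataset(feature_table(m, value_kind = value_kind), md))
}

# Hand-built mmi_result (for detector tests that control residuals exactly).
fake_mmi_result <- function(residual, times = seq_along(residual),
                            subjects = "a", mmi = residual,
                            halfwidth = Inf) {
  out <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(residual)),
    subject_id = rep_len(subjects, length(residual)),
    time = times, group = "all", mmi = mmi,
    expected_mmi = mmi - residual, residual = residual,
    halfwidth = halfwidth, within_interval = abs(residual) <= halfwidth)
  class(out) <- c("mmi_result", class(out))
  out
}

# A dataset where one feature is exactly time and the rest are noise:
# the regressor-recovery workhorse.
signal_dataset <- function(n_subjects = 12, per_subject = 5, n_noise = 9,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- n_subjects * per_subject
    times <- rep(seq(0, 2, length.out = per_subject), n_subjects)
    m <- cbind(time_copy = times,
               matrix(rnorm(n * n_noise), n, n_noise))
    colnames(m) <- c("time_copy", sprintf("noise%02d", seq_len(n_noise)))
    m <- m - min(m) + 0.01
    rownames(m) <- sprintf("s%03d", seq_len(n))
    tiny_dataset(m, times = times,
                 subjects = rep(sprintf("subj%02d", seq_len(n_subjects)),
                                each = per_subject))
  })
}

`%||%` <- rlang::`%||%`
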