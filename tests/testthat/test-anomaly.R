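test_that("interval outliers flag band exits with scaled scores", {
  # on-curve points: no outliers
  t <- rep(1:10, 3)
  withr::with_seed(41, y <- t + rnorm(30, 0, 0.5))
  curve <- fit_trajectory_curve(t, y, level = 0.95)
  on_curve <- fake_mmi_result(rep(0, 30), times = t)
  attr(on_curve, "curve") <- curve
  attr(on_curve, "interval") <- "prediction"
  on_curve$within_interval <- TRUE
  rep0 <- interval_outliers(on_curve)
  expect_equal(sum(rep0$is_outlier), 0)
  expect_equal(unique(rep0$method), "interval")

  # a point at 10 residual SDs scores ~10 and is flagged
  scale5 <- mbtraj:::residual_scale(curve, 5)
  far <- fake_mmi_result(c(rep(0, 29), 10 * scale5), times = c(t[1:29], 5))
  attr(far, "curve") <- curve
  attr(far, "interval") <- "prediction"
  far$within_interval <- abs(far$residual) <=
    interval_halfwidth(curve, far$time)
  rep10 <- interval_outliers(far)
  expect_true(rep10$is_outlier[30])
  expect_equal(rep10$score[30], 10, tolerance = 1e-6)
})

test_that("interval outlier rate on null data matches the band complement", {
  withr::with_seed(42, {
    t_tr <- runif(500, 0, 10)
    y_tr <- t_tr + rnorm(500)
    t_new <- runif(500, 0.5, 9.5)
    y_new <- t_new + rnorm(500)
  })
  curve <- fit_trajectory_curve(t_tr, y_tr, level = 0.9)
  resid <- y_new - curve_eval(curve, t_new)
  mmi <- fake_mmi_result(resid, times = t_new,
                         halfwidth = interval_halfwidth(curve, t_new))
  attr(mmi, "curve") <- curve
  attr(mmi, "interval") <- "prediction"
  attr(mmi, "level") <- 0.9
  rep <- interval_outliers(mmi)
  expect_gt(mean(rep$is_outlier), 0.06)
  expect_lt(mean(rep$is_outlier), 0.14)
})

test_that("the low-pass detector flags spikes but not drifts", {
  flat <- fake_mmi_result(rep(0.3, 20))
  expect_equal(lowpass_outliers(flat, 5, 3)$score, rep(0, 20))

  spike <- fake_mmi_result(c(rep(0, 9), 10, rep(0, 10)))
  lp <- lowpass_outliers(spike, window = 5, k = 3)
  expect_equal(which(lp$is_outlier), 10L)

  drift <- fake_mmi_result(seq(0, 3, length.out = 25))
  expect_equal(sum(lowpass_outliers(drift, 5, 3)$is_outlier), 0)

  # score is invariant to adding a constant to all residuals
  withr::with_seed(43, r <- rnorm(40))
  a <- lowpass_outliers(fake_mmi_result(r), 5, 3)
  b <- lowpass_outliers(fake_mmi_result(r + 100), 5, 3)
  expect_equal(a$score, b$score, tolerance = 1e-9)

  expect_error(lowpass_outliers(flat, window = 4), "odd")
  expect_error(lowpass_outliers(fake_mmi_result(c(1, 2)), 5), "at least 5")
})

test_that("the isolation detector obeys its contamination quantile exactly", {
  withr::with_seed(44, r <- rnorm(200))
  mmi <- fake_mmi_result(r)
  for (contamination in c(0.03, 0.05, 0.11)) {
    rep <- isolation_outliers(mmi, contamination = contamination, seed = 9)
    expect_equal(sum(rep$is_outlier), ceiling(contamination * 200))
  }
  r1 <- isolation_outliers(mmi, contamination = 0.05, seed = 9)
  r2 <- isolation_outliers(mmi, contamination = 0.05, seed = 9)
  expect_identical(r1, r2)

  # planted 3-sample burst of +8 SD is recovered in most seeded runs
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, rr <- rnorm(200))
    rr[100:102] <- 8
    flagged <- which(isolation_outliers(fake_mmi_result(rr),
                                        contamination = 0.05,
                                        seed = s)$is_outlier)
    all(100:102 %in% flagged)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("outlier explanation recovers a planted discriminating feature", {
  make_case <- function(seed, shift) {
    gen <- generate_dataset(synthetic_spec(n_subjects = 30,
                                           samples_per_subject = 5,
                                           n_features = 20, seed = seed))
    ds <- gen$dataset
    n <- nrow(ds$features)
    out_idx <- withr::with_seed(seed, sample(n, 15))
    m <- feature_matrix(ds$features)
    m[out_idx, "taxon_10"] <- m[out_idx, "taxon_10"] +
      shift * sd(m[, "taxon_10"])
    ds$features[feature_ids(ds$features)] <- m
    ds$features <- set_value_kind(ds$features, "counts")
    rep <- mbtraj:::new_anomaly_report(
      fake_mmi_result(rep(0, n), times = ds$metadata$time,
                      subjects = ds$metadata$subject_id),
      "interval", score = 0, is_outlier = seq_len(n) %in% out_idx,
      parameters = list())
    rep$sample_id <- ds$features$sample_id
    list(ds = ds, rep = rep)
  }
  case <- make_case(45, shift = 10)
  ex <- explain_outliers(case$ds, case$rep, seed = 45)
  expect_equal(ex$ranking$feature_id[1], "taxon_10")
  expect_gte(ex$auroc, 0.95)
  expect_equal(ex$n_background, 3 * ex$n_outliers)

  # random labels give chance-level AUROC
  null_auc <- vapply(1:8, function(s) {
    case0 <- make_case(200 + s, shift = 0)
    explain_outliers(case0$ds, case0$rep, seed = s)$auroc
  }, numeric(1))
  expect_gte(mean(null_auc > 0.25 & null_auc < 0.75), 0.8)

  # balanced classes with ratio 1: all samples used
  gen <- generate_dataset(synthetic_spec(n_subjects = 6,
                                         samples_per_subject = 5,
                                         n_features = 8, seed = 46))
  ds <- gen$dataset
  repb <- mbtraj:::new_anomaly_report(
    fake_mmi_result(rep(0, 30), times = ds$metadata$time,
                    subjects = ds$metadata$subject_id),
    "interval", score = 0, is_outlier = rep(c(TRUE, FALSE), 15),
    parameters = list())
  repb$sample_id <- ds$features$sample_id
  exb <- explain_outliers(ds, repb, subsample_ratio = 1, seed = 46)
  expect_equal(exb$n_outliers + exb$n_background, 30)
})
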