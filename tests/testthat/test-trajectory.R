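test_that("trajectory curves reproduce noiseless lines with empty bands", {
  t <- seq(0, 10, length.out = 40)
  y <- 2 + 0.5 * t
  curve <- fit_trajectory_curve(t, y, level = 0.95)
  expect_lt(max(abs(curve_eval(curve, t) - y)), 1e-6)
  expect_lt(max(residual_scale(curve, t)), 1e-6)

  # prediction band strictly wider than confidence band on noisy data
  withr::with_seed(31, yn <- y + rnorm(40))
  cn <- fit_trajectory_curve(t, yn, level = 0.9)
  grid <- seq(0, 10, length.out = 50)
  expect_true(all(interval_halfwidth(cn, grid, kind = "prediction") >
                    interval_halfwidth(cn, grid, kind = "confidence")))
  expect_error(fit_trajectory_curve(t[1:5], y[1:5]), ">= 10 points")
})

test_that("binned residual scales recover a homoscedastic sigma", {
  withr::with_seed(32, {
    t <- runif(500, 0, 10)
    y <- 1 + t + rnorm(500, sd = 1)
  })
  curve <- fit_trajectory_curve(t, y, level = 0.9)
  mean_scale <- mean(residual_scale(curve, seq(0.5, 9.5, length.out = 50)))
  expect_gt(mean_scale, 0.9)
  expect_lt(mean_scale, 1.1)
})

test_that("the MMI regressor recovers time and fails on shuffled labels", {
  ds <- signal_dataset(seed = 33)
  m <- fit_mmi_model(ds, "bagged_trees", seed = 33)
  expect_gte(m$cv_r2, 0.95)

  # identical seed, identical predictions
  m2 <- fit_mmi_model(ds, "bagged_trees", seed = 33)
  expect_identical(predict_mmi(m, ds)$mmi, predict_mmi(m2, ds)$mmi)

  # null: shuffled time labels give near-zero CV skill in most runs
  null_ok <- vapply(1:20, function(s) {
    ds_null <- signal_dataset(seed = 100 + s)
    ds_null$metadata$time <- withr::with_seed(s, sample(ds_null$metadata$time))
    # keep the copy feature out of sync with the shuffled labels
    fit <- fit_mmi_model(ds_null, "bagged_trees", seed = s)
    fit$cv_r2 <= 0.1
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)

  expect_error(fit_mmi_model(ds, "no_such_model"), "registry")
})

test_that("MMI predictions report residuals and interval membership", {
  ds <- signal_dataset(n_subjects = 16, seed = 34)
  ds$features$time_copy <- ds$features$time_copy +
    withr::with_seed(34, rnorm(nrow(ds$features), 0, 0.1))
  m <- fit_mmi_model(ds, "linear", seed = 34, level = 0.95)
  res <- predict_mmi(m, ds)
  expect_equal(res$residual, res$mmi - res$expected_mmi)

  # a sample displaced 10 residual-SDs lands outside the band
  ds_out <- ds
  i <- 7
  scale_i <- mbtraj:::residual_scale(m$curve, ds$metadata$time[i])
  ds_out$features$time_copy[i] <- ds_out$features$time_copy[i] + 10 * scale_i
  res_out <- predict_mmi(m, ds_out)
  expect_false(res_out$within_interval[i])

  # missing features are an error; extra features a warning
  ds_miss <- ds
  ds_miss$features <- ds$features[setdiff(names(ds$features), "noise01")]
  expect_error(predict_mmi(m, ds_miss), "noise01")
  ds_extra <- ds
  ds_extra$features$extra_feature <- 1
  expect_warning(predict_mmi(m, ds_extra), "extra feature")
})

test_that("held-out 90% prediction intervals cover near-nominally", {
  sp <- synthetic_spec(n_subjects = 60, seed = 35)
  gen <- generate_dataset(sp)
  subj <- unique(gen$dataset$metadata$subject_id)
  md <- gen$dataset$metadata
  tr <- md$sample_id[md$subject_id %in% subj[1:40]]
  te <- setdiff(md$sample_id, tr)
  m <- fit_mmi_model(mbtraj:::dataset_subset(gen$dataset, tr),
                     level = 0.9, seed = 35)
  res <- predict_mmi(m, mbtraj:::dataset_subset(gen$dataset, te))
  expect_gt(mean(res$within_interval), 0.82)
  expect_lt(mean(res$within_interval), 0.98)
})

test_that("Shapley importances satisfy local accuracy and isolate signals", {
  ds <- signal_dataset(n_subjects = 10, seed = 36)
  m <- fit_mmi_model(ds, "bagged_trees", seed = 36)
  shap <- mbtraj:::model_shapley(m, ds, n_perm = 6)
  # local accuracy: attributions + base value = prediction
  expect_lt(max(abs(rowSums(shap$values) + shap$base_value -
                      shap$prediction)), 1e-6)
  imp <- feature_importance_over_time(m, ds, list(c(0, 2)))
  expect_gte(imp$importance[imp$feature_id == "time_copy"] /
               sum(imp$importance), 0.9)

  # two features informative in disjoint time halves dominate their windows
  withr::with_seed(37, {
    n <- 80
    t2 <- rep(seq(0, 2, length.out = 8), 10)
    early <- ifelse(t2 < 1, t2, 1) + rnorm(n, 0, 0.01)
    late <- ifelse(t2 >= 1, t2 - 1, 0) + rnorm(n, 0, 0.01)
    noise <- matrix(abs(rnorm(n * 3)) + 0.01, n, 3)
  })
  m2 <- cbind(early = early - min(early) + 0.01,
              late = late - min(late) + 0.01, noise)
  colnames(m2)[3:5] <- sprintf("nz%d", 1:3)
  ds2 <- tiny_dataset(m2, times = t2,
                      subjects = rep(sprintf("m%d", 1:10), each = 8))
  mr <- fit_mmi_model(ds2, "bagged_trees", seed = 37)
  imp2 <- feature_importance_over_time(mr, ds2, list(c(0, 1), c(1, 2)))
  w1 <- imp2[imp2$window == 1, ]
  w2 <- imp2[imp2$window == 2, ]
  expect_equal(w1$feature_id[which.max(w1$importance)], "early")
  expect_equal(w2$feature_id[which.max(w2$importance)], "late")

  expect_warning(feature_importance_over_time(mr, ds2, list(c(5, 6))),
                 "no samples")
})

test_that("the leaderboard ranks by skill with identical folds", {
  ds <- signal_dataset(seed = 38)
  lb <- compare_models(ds, c("tree", "dummy", "tree"), cv_folds = 4,
                       seed = 38)
  expect_equal(nrow(lb), 3)
  expect_equal(lb$model[1], "tree")
  expect_lte(lb$mean_r2[lb$model == "dummy"][1], 0)
  # the duplicated model scores identically (same folds, same seed)
  trees <- lb[lb$model == "tree", ]
  expect_equal(trees$mean_r2[1], trees$mean_r2[2])
  expect_equal(trees$mean_mae[1], trees$mean_mae[2])
  expect_false(any(lb$failed))
  expect_true(nchar(attr(lb, "fold_hash")) > 0)
})

test_that("identical groups are not separated; shifted groups are", {
  ds <- signal_dataset(n_subjects = 12, per_subject = 6, seed = 39)
  # noisy copy of time so the MMI has a non-trivial residual scale
  ds$features$time_copy <- ds$features$time_copy +
    withr::with_seed(40, rnorm(nrow(ds$features), 0, 0.2))
  # group B: exact duplicate of group A under fresh subject ids
  feats <- feature_matrix(ds$features)
  dup <- feats
  rownames(dup) <- paste0("dup_", rownames(dup))
  md2 <- ds$metadata
  md2$sample_id <- paste0("dup_", md2$sample_id)
  md2$subject_id <- paste0("dup_", md2$subject_id)
  md2$group <- "B"
  both <- tiny_dataset(rbind(feats, dup),
                       times = c(ds$metadata$time, md2$time),
                       subjects = c(ds$metadata$subject_id, md2$subject_id),
                       groups = c(rep("A", nrow(feats)), md2$group),
                       value_kind = "counts")
  m <- fit_mmi_model(both, "linear", seed = 39)
  lin <- compare_trajectories(both, m, "A", "B", "linear")
  expect_gt(lin$p_value, 0.9)
  perm <- compare_trajectories(both, m, "A", "B", "spline_permutation",
                               n_permutations = 99, seed = 1)
  expect_gte(perm$p_value, 0.5)

  # group B shifted upward by ~5 residual SDs: both methods reject
  res <- predict_mmi(m, both)
  sd_res <- sd(res$residual)
  shifted <- both
  sel <- shifted$metadata$group == "B"
  shifted$features$time_copy[sel] <- shifted$features$time_copy[sel] +
    5 * sd_res
  m_s <- fit_mmi_model(shifted, "linear", seed = 39)
  lin_s <- compare_trajectories(shifted, m_s, "A", "B", "linear")
  perm_s <- compare_trajectories(shifted, m_s, "A", "B",
                                 "spline_permutation",
                                 n_permutations = 999, seed = 2)
  expect_lte(lin_s$p_value, 0.01)
  expect_lte(perm_s$p_value, 0.01)
  # permutation p attains its lower bound when observed beats all nulls
  expect_equal(perm_s$p_value, 1 / 1000)
})
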