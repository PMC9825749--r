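test_that("closure to relative abundances conserves unit row sums", {
  ft <- feature_table(tibble::tibble(sample_id = c("a", "b"),
                                     f1 = c(2, 10), f2 = c(2, 0),
                                     f3 = c(0, 0)))
  rel <- to_relative_abundance(ft)
  expect_equal(unname(feature_matrix(rel)[1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(feature_matrix(rel)[2, ]), c(1, 0, 0))
  expect_equal(value_kind(rel), "relative")

  withr::with_seed(21, big <- matrix(rpois(50 * 30, 20) + 1, 50, 30))
  rel2 <- to_relative_abundance(feature_table(big))
  expect_lt(max(abs(rowSums(feature_matrix(rel2)) - 1)), 1e-12)

  zero <- feature_table(tibble::tibble(sample_id = c("a", "b"),
                                       f1 = c(1, 0), f2 = c(1, 0)))
  expect_error(to_relative_abundance(zero), "sample 'b'")
})

test_that("feature filtering removes low-variance then correlated features", {
  withr::with_seed(22, {
    a <- rnorm(50, 10, 2)
    m <- cbind(constant = rep(5, 50), A = a, B = 2 * a,
               C = rnorm(50, 10, 3), D = rnorm(50, 10, 3))
  })
  m <- abs(m) + 0.01
  ft <- feature_table(m)
  out <- filter_features(ft, variance_quantile = 0.1,
                         correlation_threshold = 0.99)
  log <- removal_log(out)
  expect_equal(log$reason[log$feature_id == "constant"], "low_variance")
  # B = 2A exactly: the lower-variance member (A) goes
  expect_true("A" %in% log$feature_id[log$reason == "correlated"])
  expect_true("B" %in% feature_ids(out))

  # deterministic: identical inputs give identical removal logs
  out2 <- filter_features(ft, 0.1, 0.99)
  expect_identical(removal_log(out2), log)

  # independent noise features: no correlation removals in most seeded runs
  clean_runs <- vapply(1:40, function(s) {
    withr::with_seed(s, noise <- abs(matrix(rnorm(60 * 20), 60, 20)) + 0.01)
    f <- filter_features(feature_table(noise), 0, 0.99)
    sum(removal_log(f)$reason == "correlated") == 0
  }, logical(1))
  expect_gte(mean(clean_runs), 0.95)

})

test_that("log-ratio transform is compositionally coherent", {
  m <- matrix(c(4, 8, 2, 4, 3, 5), nrow = 2,
              dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  ft <- feature_table(m)
  lr <- log_ratio_transform(ft, "f2", pseudocount = 0)
  expect_equal(feature_ids(lr), c("f1", "f3"))
  expect_equal(lr$f1, c(log(2), log(2)))
  expect_equal(value_kind(lr), "logratio")

  # a feature equal to the denominator maps to an all-zero column
  ft_eq <- feature_table(cbind(m, f4 = m[, "f2"]))
  lr_eq <- log_ratio_transform(ft_eq, "f2", pseudocount = 0)
  expect_equal(lr_eq$f4, c(0, 0))

  # per-sample scale invariance with zero pseudocount on positive data
  m_scaled <- m
  m_scaled[1, ] <- m[1, ] * 10
  lr_scaled <- log_ratio_transform(feature_table(m_scaled), "f2",
                                   pseudocount = 0)
  expect_equal(feature_matrix(lr_scaled), feature_matrix(lr),
               tolerance = 1e-12)

  expect_error(log_ratio_transform(ft, "f9"), "nearest feature ids")
})

test_that("crossing counts match a brute-force pairwise oracle", {
  # parallel trajectories: zero crossings; one intersection: one crossing
  m_flat <- rbind(c(0.5, 0.2, 0.3), c(0.5, 0.2, 0.3),
                  c(0.5, 0.2, 0.3), c(0.5, 0.2, 0.3))
  colnames(m_flat) <- c("cand", "low", "rest")
  ds_flat <- tiny_dataset(m_flat, times = c(0, 0, 1, 1),
                          value_kind = "relative")
  expect_equal(count_crossings(ds_flat, "cand", n_bins = 2), 0)

  m_cross <- rbind(c(0.5, 0.2, 0.3), c(0.5, 0.2, 0.3),
                   c(0.35, 0.5, 0.15), c(0.35, 0.5, 0.15))
  colnames(m_cross) <- c("cand", "riser", "rest")
  ds_cross <- tiny_dataset(m_cross, times = c(0, 0, 1, 1),
                           value_kind = "relative")
  expect_equal(count_crossings(ds_cross, "cand", n_bins = 2), 1)

  # random dataset vs an independent per-pair sign-change count
  withr::with_seed(23, m <- matrix(rexp(60 * 10), 60, 10))
  m <- m / rowSums(m)
  colnames(m) <- sprintf("t%02d", 1:10)
  times <- rep(seq(0, 2, length.out = 6), 10)
  ds <- tiny_dataset(m, times = times, value_kind = "relative")
  n_bins <- 5
  breaks <- seq(0, 2, length.out = n_bins + 1)
  idx <- pmin(findInterval(times, breaks, rightmost.closed = TRUE), n_bins)
  med <- sapply(sort(unique(idx)), function(b) {
    apply(m[idx == b, , drop = FALSE], 2, median)
  })
  for (cand in c("t01", "t05", "t10")) {
    oracle <- sum(vapply(setdiff(colnames(m), cand), function(f) {
      s <- sign(med[f, ] - med[cand, ])
      s <- s[s != 0]
      if (length(s) < 2) 0L else sum(s[-1] != s[-length(s)])
    }, integer(1)))
    expect_equal(count_crossings(ds, cand, n_bins = n_bins), oracle)
  }
})

test_that("differential ranking is a Spearman correlation with time", {
  # deterministic monotone composition: shares are exact functions of time
  times <- seq(0, 2, length.out = 30)
  m <- cbind(up = exp(times), down = exp(-times), n1 = rep(1, 30),
             n2 = rep(2, 30))
  ds <- tiny_dataset(m / rowSums(m), times = times,
                     subjects = rep(sprintf("m%d", 1:5), each = 6),
                     value_kind = "relative")
  dr <- differential_ranking(ds)
  expect_equal(dr$ranking[dr$feature_id == "up"], 1, tolerance = 1e-12)
  expect_equal(dr$ranking[dr$feature_id == "down"], -1, tolerance = 1e-12)

  # null features rarely show |rho| above 0.2 at n = 200
  null_ok <- vapply(1:100, function(s) {
    withr::with_seed(400 + s, {
      x <- abs(rnorm(200)) + 0.01
      t <- rep(1:20, 10)
    })
    abs(cor(x, t, method = "spearman")) < 0.2
  }, logical(1))
  expect_gte(mean(null_ok), 0.95)
})

test_that("denominator selection strategies pick the constructed optimum", {
  # A rises, B falls (they cross once at t = 1); C stays far below both,
  # so C is the only candidate whose differences never change sign.
  times <- rep(seq(0, 2, length.out = 6), 8)
  withr::with_seed(25, jitter <- abs(matrix(rnorm(48 * 3, 0, 0.01), 48, 3)))
  m <- cbind(A = exp(times) + jitter[, 1],
             B = exp(2 - times) + jitter[, 2],
             C = 0.05 + jitter[, 3])
  ds <- tiny_dataset(m / rowSums(m),
                     times = times,
                     subjects = rep(sprintf("m%d", 1:8), each = 6),
                     value_kind = "relative")
  expect_equal(select_denominator(ds, "crossings")$feature_id, "C")
  expect_equal(select_denominator(ds, "ranking_high")$feature_id, "A")
  expect_equal(select_denominator(ds, "ranking_low")$feature_id, "B")
})

test_that("performance-based denominator selection equals exhaustive search", {
  for (seed in 1:2) {
    sp <- synthetic_spec(n_subjects = 12, samples_per_subject = 5,
                         n_features = 8, n_informative = 3, seed = seed)
    ds <- generate_dataset(sp)$dataset
    rep <- select_denominator(ds, "performance", model = "tree",
                              cv_folds = 4, seed = seed)
    feats <- feature_ids(ds$features)
    oracle_scores <- vapply(feats, function(f) {
      lr <- log_ratio_transform(ds$features, f)
      folds <- grouped_folds(ds$metadata$subject_id, 4, seed = seed)
      mean(vapply(sort(unique(folds)), function(k) {
        tr <- folds != k
        X <- feature_matrix(lr)
        df <- as.data.frame(X); df$y <- ds$metadata$time
        fit <- rpart::rpart(y ~ ., df[tr, ], method = "anova")
        pred <- predict(fit, df[!tr, ])
        1 - sum((df$y[!tr] - pred)^2) / sum((df$y[!tr] - mean(df$y[!tr]))^2)
      }, numeric(1)))
    }, numeric(1))
    best <- sort(names(oracle_scores)[oracle_scores == max(oracle_scores)])[1]
    expect_equal(rep$feature_id, best)
    expect_equal(nrow(rep$scores), 8)
  }
})

test_that("hybrid feature sets union model and domain features in order", {
  imp <- c(a = 0.5, b = 0.3, c = 0.1)
  expect_equal(build_hybrid_feature_set(imp, 2, "c"), c("a", "b", "c"))
  expect_equal(build_hybrid_feature_set(imp, 2, "a"), c("a", "b"))
  expect_equal(build_hybrid_feature_set(imp, 2), c("a", "b"))
  expect_error(build_hybrid_feature_set(imp, 2, "zzz"), "unknown domain")
})

test_that("reference definition admits duplicates and rejects shifted samples", {
  gen <- generate_dataset(synthetic_spec(n_subjects = 8,
                                         samples_per_subject = 5,
                                         n_features = 10, seed = 26))
  ds <- gen$dataset
  ref_g <- define_reference(ds, "group_label", reference_group = "control")
  expect_true(all(ref_g$is_reference == (ds$metadata$group == "control")))

  # seed set plus exact duplicates: duplicates admitted
  m <- feature_matrix(ds$features)
  dup <- m[1:6, , drop = FALSE]
  rownames(dup) <- paste0("dup", 1:6)
  ds_dup <- tiny_dataset(rbind(m, dup),
                         times = c(ds$metadata$time, ds$metadata$time[1:6]),
                         subjects = c(ds$metadata$subject_id,
                                      rep("dupsubj", 6)),
                         value_kind = "counts")
  ds_dup$metadata$is_reference <- c(rep(TRUE, nrow(m)), rep(FALSE, 6))
  ref_n <- define_reference(ds_dup, "novelty", novelty_frac = 0.1, seed = 1)
  admitted <- ref_n$is_reference[ds_dup$metadata$subject_id == "dupsubj"]
  expect_true(all(admitted))

  # +10 SD shifted samples are not admitted in nearly all seeded runs
  rejected <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      shift <- m[1:4, , drop = FALSE]
      shift[, 1:5] <- shift[, 1:5] + 10 * matrix(apply(m[, 1:5], 2, sd),
                                                 4, 5, byrow = TRUE)
    })
    rownames(shift) <- paste0("shift", 1:4)
    dss <- tiny_dataset(rbind(m, shift),
                        times = c(ds$metadata$time, ds$metadata$time[1:4]),
                        subjects = c(ds$metadata$subject_id, rep("shf", 4)),
                        value_kind = "counts")
    dss$metadata$is_reference <- c(rep(TRUE, nrow(m)), rep(FALSE, 4))
    r <- define_reference(dss, "novelty", novelty_frac = 0.1, seed = s)
    !any(r$is_reference[dss$metadata$subject_id == "shf"])
  }, logical(1))
  expect_gte(mean(rejected), 0.95)

  small <- tiny_dataset(matrix(1:12 + 0.5, 6, 2),
                        times = rep(0:2, 2),
                        subjects = rep(c("x", "y"), each = 3))
  small$metadata$is_reference <- TRUE
  expect_error(define_reference(small, "declared"), ">= 10")
})
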