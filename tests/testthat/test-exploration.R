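test_that("sampling statistics bin and count conservatively", {
  m <- matrix(1, 6, 2)
  ds <- tiny_dataset(m, times = c(0, 0, 1, 1, 2, 2),
                     subjects = c("a", "a", "a", "a", "a", "b"))
  ss <- sampling_statistics(ds, n_bins = 2)
  expect_equal(ss$per_timebin$n_samples, c(2L, 4L)) # [0,1) and [1,2]
  expect_equal(sum(ss$per_timebin$n_samples), 6L)
  expect_equal(ss$per_subject$n_samples[ss$per_subject$subject_id == "a"], 5L)

  gen <- generate_dataset(synthetic_spec(n_subjects = 6,
                                         samples_per_subject = 5,
                                         n_features = 5, seed = 2))
  for (b in c(1, 3, 7)) {
    ss2 <- sampling_statistics(gen$dataset, n_bins = b)
    expect_equal(sum(ss2$per_timebin$n_samples), 30L)
    expect_equal(sum(ss2$per_subject$n_samples), 30L)
  }
})

test_that("alpha diversity matches closed forms and the direct-sum oracle", {
  ft <- feature_table(tibble::tibble(sample_id = c("u", "v"),
                                     f1 = c(0.25, 1), f2 = c(0.25, 0),
                                     f3 = c(0.25, 0), f4 = c(0.25, 0)),
                      value_kind = "relative")
  sh <- alpha_diversity(ft, "shannon")
  expect_equal(sh$diversity[1], log(4), tolerance = 1e-12)
  expect_equal(sh$diversity[2], 0)
  si <- alpha_diversity(ft, "simpson")
  expect_equal(si$diversity, c(1 - 4 * 0.25^2, 0), tolerance = 1e-12)

  withr::with_seed(7, {
    p <- matrix(rexp(50), 5, 10)
    p <- p / rowSums(p)
  })
  rownames(p) <- sprintf("s%d", 1:5)
  ftr <- feature_table(p, value_kind = "relative")
  oracle <- apply(p, 1, function(q) -sum(q[q > 0] * log(q[q > 0])))
  expect_lt(max(abs(alpha_diversity(ftr, "shannon")$diversity - oracle)),
            1e-12)
  # Simpson bounded by 1 - 1/K; Shannon maximal iff uniform
  expect_true(all(alpha_diversity(ftr, "simpson")$diversity <= 1 - 1 / 10))
  expect_true(all(alpha_diversity(ftr, "shannon")$diversity < log(10)))

  lr <- set_value_kind(ftr, "logratio")
  expect_error(alpha_diversity(lr), "undefined")
})

test_that("PCA embeddings are exact principal-component scores", {
  withr::with_seed(5, {
    line <- outer(rnorm(30), c(1, 2, 3, 4, 5)) # rank-1 data in 5-D
    line <- line - min(line) + 0.1
  })
  ds <- tiny_dataset(line)
  emb <- embed_samples(ds, "pca", n_dims = 2)
  expect_lt(var(emb$dim2), 1e-20 * var(emb$dim1)) # second component empty

  withr::with_seed(6, m <- matrix(rexp(40 * 5), 40, 5))
  m <- cbind(m, m[, 1] + m[, 2]) # rank-5 data in 6-D
  ds2 <- tiny_dataset(m)
  full <- embed_samples(ds2, "pca", n_dims = 5)
  centered <- scale(feature_matrix(ds2$features), scale = FALSE)
  expect_equal(sum(apply(full[-1], 2, var)), sum(apply(centered, 2, var)),
               tolerance = 1e-9)
  # scores are an isometry of the centered data: distances are preserved
  expect_equal(as.numeric(dist(as.matrix(full[-1]))),
               as.numeric(dist(centered)), tolerance = 1e-9)
  expect_error(embed_samples(ds2, "pca", n_dims = 6), "below the feature count")
})

test_that("nonlinear embeddings are deterministic under a seed", {
  withr::with_seed(8, m <- matrix(rexp(60 * 5), 60, 5))
  ds <- tiny_dataset(m)
  for (method in c("tsne", "spectral")) {
    e1 <- embed_samples(ds, method, n_dims = 2, seed = 11)
    e2 <- embed_samples(ds, method, n_dims = 2, seed = 11)
    expect_identical(e1, e2)
  }
})

test_that("outlier clusters are found and their planted feature recovered", {
  withr::with_seed(9, {
    main <- matrix(rnorm(95 * 5, mean = 5, sd = 1), 95, 5)
    blob <- matrix(rnorm(5 * 5, mean = 5, sd = 0.3), 5, 5)
    blob[, 3] <- blob[, 3] + 10 # shifted +10 SD in feature 3
    m <- abs(rbind(main, blob)) + 0.01
  })
  ds <- tiny_dataset(m)
  emb <- embed_samples(ds, "pca", 2)
  oc <- embedding_outlier_clusters(emb, ds, min_cluster_frac = 0.2)
  sizes <- table(oc$assignments$cluster[oc$assignments$is_outlier_cluster])
  expect_length(sizes, 1)
  expect_equal(unname(sizes[1]), 5L)
  expect_true(all(which(oc$assignments$is_outlier_cluster) %in% 96:100))
  top <- oc$tests[[1]]$feature_id[which.min(oc$tests[[1]]$q_value)]
  expect_equal(top, "f03")

  # a single blob yields no outlier clusters and no error
  ds1 <- tiny_dataset(abs(matrix(rnorm(80 * 4, 5), 80, 4)) + 0.01)
  oc1 <- embedding_outlier_clusters(embed_samples(ds1, "pca", 2), ds1,
                                    min_cluster_frac = 0.2)
  expect_length(oc1$tests, 0)
})

test_that("the rank-based two-group test matches exact enumeration at 3 vs 3", {
  ft <- feature_table(tibble::tibble(sample_id = letters[1:6],
                                     f1 = c(1, 2, 3, 4, 5, 6),
                                     f2 = rep(2, 6)))
  md <- tibble::tibble(sample_id = letters[1:6], subject_id = letters[1:6],
                       time = rep(0:2, 2), group = rep(c("A", "B"), each = 3))
  ds <- mb_dataset(ft, md)
  tt <- two_group_feature_test(ds, "A", "B")

  # oracle: exhaustive enumeration of all C(6,3) = 20 label splits
  vals <- c(1, 2, 3, 4, 5, 6)
  u_of <- function(a_idx) {
    a <- vals[a_idx]; b <- vals[-a_idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  splits <- utils::combn(6, 3)
  u_null <- apply(splits, 2, u_of)
  u_obs <- u_of(1:3)
  p_exact <- mean(abs(u_null - 4.5) >= abs(u_obs - 4.5))
  expect_equal(u_obs, 0)
  expect_equal(p_exact, 0.1)
  f1 <- tt[tt$feature_id == "f1", ]
  expect_equal(f1$statistic, 0)
  expect_equal(f1$p_value, p_exact, tolerance = 1e-12)
  expect_equal(f1$direction, -1)
  # identical feature: p = 1
  expect_equal(tt$p_value[tt$feature_id == "f2"], 1)

  expect_error(two_group_feature_test(ds, "A", "Z"), "available labels")
})

test_that("a planted 3-SD feature attains the best q-value among 100 nulls", {
  withr::with_seed(12, {
    m <- matrix(abs(rnorm(40 * 101)) + 0.01, 40, 101)
    m[21:40, 101] <- m[21:40, 101] + 3
  })
  colnames(m) <- c(sprintf("null%03d", 1:100), "planted")
  ds <- tiny_dataset(m, groups = rep(c("A", "B"), each = 20))
  tt <- two_group_feature_test(ds, "A", "B")
  expect_equal(tt$feature_id[which.min(tt$q_value)], "planted")
  # BH q-values are a monotone step-up transform of the sorted p-values
  ord <- order(tt$p_value)
  expect_true(all(diff(tt$q_value[ord]) >= -1e-12))
})
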