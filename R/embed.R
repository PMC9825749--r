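#' Low-dimensional embedding of samples
#'
#' Projects the samples x features matrix into `n_dims` coordinates.
#' `"pca"` returns exact principal-component scores of the mean-centered
#' matrix. `"tsne"` is an exact (quadratic-cost) t-SNE with seeded random
#' initialization, suited to the hundreds-of-samples scale of longitudinal
#' microbiome studies. `"spectral"` is a neighbourhood-graph (UMAP-like)
#' Laplacian eigenmap: symmetrized k-nearest-neighbour adjacency, embedded
#' with the smallest non-trivial eigenvectors of the normalized Laplacian.
#'
#' @param ds an [mb_dataset()].
#' @param method `"pca"`, `"tsne"` or `"spectral"`.
#' @param n_dims embedding dimension, strictly below the feature count.
#' @param seed integer seed (all methods are deterministic given it).
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param k_neighbours neighbourhood size for the spectral method.
#' @return tibble: sample_id, dim1..dim`n_dims`.
#' @export
embed_samples <- function(ds, method = c("pca", "tsne", "spectral"),
                          n_dims = 2, seed = 42, perplexity = 30,
                          k_neighbours = 15) {
  method <- match.arg(method)
  m <- feature_matrix(ds$features)
  if (n_dims >= ncol(m)) {
    stopf("n_dims (%d) must be below the feature count (%d)", n_dims, ncol(m))
  }
  coords <- switch(method,
    pca = {
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      pc$x[, seq_len(n_dims), drop = FALSE]
    },
    tsne = tsne_exact(m, n_dims = n_dims, seed = seed,
                      perplexity = perplexity),
    spectral = spectral_embed(m, n_dims = n_dims, k = k_neighbours)
  )
  out <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(n_dims))
  dplyr::bind_cols(tibble::tibble(sample_id = ds$features$sample_id), out)
}

# Exact t-SNE (O(n^2)); standard formulation: perplexity-calibrated
# Gaussian affinities, Student-t low-dimensional kernel, momentum gradient
# descent with early exaggeration.
tsne_exact <- function(x, n_dims = 2, seed = 42, perplexity = 30,
                       n_iter = 300, eta = 100) {
  n <- nrow(x)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) stopf("too few samples for t-SNE")
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- with_seed(seed, matrix(stats::rnorm(n * n_dims, sd = 1e-4), n, n_dims))
  inc <- matrix(0, n, n_dims)
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    momentum <- if (it <= 20) 0.5 else 0.8
    yd2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + yd2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% y - L %*% y)
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

# Laplacian eigenmap on a symmetrized kNN graph (UMAP-like neighbourhood
# embedding, fully deterministic).
spectral_embed <- function(x, n_dims = 2, k = 15) {
  n <- nrow(x)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(x))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k + 1)]
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))
  deg <- pmax(rowSums(A), 1e-12)
  Lsym <- diag(n) - diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  eg <- eigen(Lsym, symmetric = TRUE)
  idx <- order(eg$values)[2:(n_dims + 1)]
  v <- eg$vectors[, idx, drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(v))) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s != 0) v[, j] <- v[, j] * s
  }
  v
}

# DBSCAN (O(n^2)); eps defaults to a k-distance heuristic.
dbscan_cluster <- function(x, eps = NULL, min_pts = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  if (is.null(eps)) {
    kdist <- apply(d, 1, function(r) sort(r)[min(min_pts + 1, n)])
    eps <- unname(quantile(kdist, 0.9))
  }
  labels <- integer(n) # 0 = noise/unvisited
  visited <- logical(n)
  cl <- 0L
  neighbours <- function(i) which(d[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_pts) next # provisional noise
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_pts) queue <- union(queue, setdiff(nbj, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  list(labels = labels, eps = eps, min_pts = min_pts)
}

#' Outlier clusters in an embedding
#'
#' Density-based (DBSCAN-style) clustering of the embedded samples; every
#' cluster whose size fraction is below `min_cluster_frac` is flagged an
#' outlier cluster, and for each one a two-group differential feature test
#' (cluster versus all other samples) identifies its discriminating
#' features.
#'
#' @param embedding tibble from [embed_samples()] (or matrix with rows
#'   matching the dataset's samples).
#' @param ds the originating [mb_dataset()].
#' @param min_cluster_frac clusters smaller than this fraction of all
#'   samples are outlier clusters; in (0, 0.5).
#' @param eps DBSCAN radius; `NULL` uses the k-distance heuristic.
#' @param min_pts DBSCAN core-point threshold.
#' @return class `mb_outlier_clusters`: list with `assignments` tibble
#'   (sample_id, cluster, is_noise, is_outlier_cluster) and `tests`, a
#'   named list (one tibble per outlier cluster) of
#'   [two_group_feature_test()] results.
#' @export
embedding_outlier_clusters <- function(embedding, ds, min_cluster_frac = 0.2,
                                       eps = NULL, min_pts = 5) {
  if (min_cluster_frac <= 0 || min_cluster_frac >= 0.5) {
    stopf("min_cluster_frac must be in (0, 0.5)")
  }
  coords <- if (is.data.frame(embedding)) {
    as.matrix(embedding[setdiff(names(embedding), "sample_id")])
  } else {
    as.matrix(embedding)
  }
  if (nrow(coords) != nrow(ds$features)) {
    stopf("embedding rows (%d) do not match dataset samples (%d)",
          nrow(coords), nrow(ds$features))
  }
  db <- dbscan_cluster(coords, eps = eps, min_pts = min_pts)
  n <- nrow(coords)
  sizes <- table(db$labels[db$labels > 0])
  outlier_cl <- as.integer(names(sizes)[sizes / n < min_cluster_frac])
  assignments <- tibble::tibble(
    sample_id = ds$features$sample_id,
    cluster = db$labels,
    is_noise = db$labels == 0L,
    is_outlier_cluster = db$labels %in% outlier_cl)
  tests <- list()
  for (cl in outlier_cl) {
    in_cl <- db$labels == cl
    if (sum(in_cl) < 3 || sum(!in_cl) < 3) next
    ds_cl <- ds
    ds_cl$metadata$group <- ifelse(in_cl, "outlier_cluster", "rest")
    tests[[as.character(cl)]] <-
      two_group_feature_test(ds_cl, "outlier_cluster", "rest")
  }
  structure(list(assignments = assignments, tests = tests,
                 eps = db$eps, min_pts = min_pts,
                 min_cluster_frac = min_cluster_frac),
            class = "mb_outlier_clusters")
}

#' @export
print.mb_outlier_clusters <- function(x, ...) {
  k <- length(unique(x$assignments$cluster[x$assignments$cluster > 0]))
  cat(sprintf("<mb_outlier_clusters> %d cluster(s), %d outlier cluster(s), %d noise point(s)\n",
              k, length(x$tests), sum(x$assignments$is_noise)))
  invisible(x)
}
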