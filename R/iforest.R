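# Isolation Forest: random axis-aligned splits isolate anomalies in few
# steps; anomaly score 2^(-E[path length]/c(psi)) approaches 1 for points
# isolated much faster than average.

# Average unsuccessful-search path length of a BST with n nodes.
iforest_c <- function(n) {
  ifelse(n <= 1, 0,
         ifelse(n == 2, 1,
                2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n))
}

#' Fit an Isolation Forest
#'
#' @param x numeric matrix, observations x features.
#' @param n_trees number of isolation trees.
#' @param sample_size subsample size per tree (capped at `nrow(x)`).
#' @param seed integer seed.
#' @return class `mb_iforest`. Score new data with [isolation_score()]
#'   (larger = more anomalous, in (0, 1)).
#' @export
isolation_forest <- function(x, n_trees = 100, sample_size = 256, seed = 42) {
  x <- as.matrix(x)
  psi <- min(sample_size, nrow(x))
  limit <- ceiling(log2(max(2, psi)))
  build <- function(idx, depth) {
    if (depth >= limit || length(idx) <= 1) {
      return(list(size = length(idx)))
    }
    sub <- x[idx, , drop = FALSE]
    rng <- apply(sub, 2, range)
    usable <- which(rng[2, ] > rng[1, ])
    if (length(usable) == 0) return(list(size = length(idx)))
    q <- if (length(usable) == 1) usable else sample(usable, 1)
    p <- stats::runif(1, rng[1, q], rng[2, q])
    left <- idx[x[idx, q] < p]
    right <- setdiff(idx, left)
    if (length(left) == 0 || length(right) == 0) {
      return(list(size = length(idx)))
    }
    list(q = q, p = p,
         left = build(left, depth + 1), right = build(right, depth + 1))
  }
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      idx <- sample(nrow(x), psi)
      build(idx, 0)
    })
  })
  structure(list(trees = trees, psi = psi), class = "mb_iforest")
}

# Vectorized path length: route all rows through a tree at once.
iforest_paths <- function(node, x, idx, depth, out) {
  if (is.null(node$q)) {
    out[idx] <- depth + iforest_c(node$size)
    return(out)
  }
  go_left <- x[idx, node$q] < node$p
  if (any(go_left)) {
    out <- iforest_paths(node$left, x, idx[go_left], depth + 1, out)
  }
  if (any(!go_left)) {
    out <- iforest_paths(node$right, x, idx[!go_left], depth + 1, out)
  }
  out
}

#' @rdname isolation_forest
#' @param forest a fitted `mb_iforest`.
#' @param newdata numeric matrix to score (same columns as the training x).
#' @export
isolation_score <- function(forest, newdata) {
  newdata <- as.matrix(newdata)
  paths <- vapply(forest$trees, function(tr) {
    iforest_paths(tr, newdata, seq_len(nrow(newdata)), 0,
                  numeric(nrow(newdata)))
  }, numeric(nrow(newdata)))
  if (is.null(dim(paths))) paths <- matrix(paths, nrow = nrow(newdata))
  avg <- rowMeans(paths)
  2^(-avg / iforest_c(forest$psi))
}
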