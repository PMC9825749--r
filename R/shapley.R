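#' Shapley-value attributions by permutation sampling
#'
#' Estimates per-feature Shapley attributions of a prediction function with
#' the marginal (background-interventional) value function: features are
#' inserted one at a time in seeded random orders, each feature credited
#' with the change in the mean prediction over the background rows. Because
#' contributions telescope along every insertion order, the attributions of
#' each sample sum exactly to `prediction - base_value` (local accuracy),
#' for any number of sampled permutations.
#'
#' @param predict_fun function taking a numeric matrix and returning a
#'   numeric vector of predictions.
#' @param X numeric matrix of samples to explain (rows).
#' @param background numeric matrix of reference rows defining the baseline
#'   distribution (same columns as `X`).
#' @param n_perm number of sampled feature orders.
#' @param seed integer seed for the permutation draw.
#' @return class `mb_shapley`: list with `values` (matrix, same shape as
#'   `X`), `base_value` (mean background prediction) and `prediction`
#'   (per-row model output).
#' @export
shapley_values <- function(predict_fun, X, background, n_perm = 8, seed = 42) {
  X <- as.matrix(X)
  background <- as.matrix(background)
  p <- ncol(X)
  if (ncol(background) != p) stopf("background columns do not match X")
  B <- nrow(background)
  perms <- with_seed(seed, replicate(n_perm, sample(p), simplify = FALSE))
  base_value <- mean(predict_fun(background))
  values <- matrix(0, nrow(X), p, dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    # all intermediate coalitions for all permutations, one predict call
    blocks <- vector("list", n_perm)
    for (k in seq_len(n_perm)) {
      z <- background
      states <- matrix(0, p * B, p)
      for (j in seq_len(p)) {
        z[, perms[[k]][j]] <- X[i, perms[[k]][j]]
        states[((j - 1) * B + 1):(j * B), ] <- z
      }
      blocks[[k]] <- states
    }
    stacked <- do.call(rbind, blocks)
    colnames(stacked) <- colnames(background)
    preds <- predict_fun(stacked)
    phi <- numeric(p)
    for (k in seq_len(n_perm)) {
      off <- (k - 1) * p * B
      step_means <- vapply(seq_len(p), function(j) {
        mean(preds[(off + (j - 1) * B + 1):(off + j * B)])
      }, numeric(1))
      contrib <- diff(c(base_value, step_means))
      phi[perms[[k]]] <- phi[perms[[k]]] + contrib
    }
    values[i, ] <- phi / n_perm
  }
  structure(list(values = values, base_value = base_value,
                 prediction = predict_fun(X)),
            class = "mb_shapley")
}
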