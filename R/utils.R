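# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats median mad sd var cor quantile predict setNames
NULL

# Seeded evaluation that never leaks into the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed; kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}

#' Grouped cross-validation folds
#'
#' Assigns groups (typically subjects) to `k` folds so that all observations
#' of one group share a fold. Groups are shuffled with the seed and dealt
#' round-robin, which balances fold sizes in groups.
#'
#' @param group character or factor vector, one entry per observation.
#' @param k number of folds; capped at the number of distinct groups.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids (1..k), one per observation, with the
#'   fold assignment of each distinct group in `attr(, "group_folds")`.
#' @export
grouped_folds <- function(group, k = 5, seed = 42) {
  group <- as.character(group)
  levels <- unique(group)
  k <- min(k, length(levels))
  shuffled <- with_seed(seed, sample(levels))
  fold_of <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  out <- unname(fold_of[group])
  attr(out, "group_folds") <- fold_of
  out
}

# Deterministic fingerprint of a fold assignment (used to assert identical
# folds across leaderboard models).
fold_hash <- function(folds) {
  paste(folds, collapse = ",")
}

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

# Rank-based AUROC (probability a positive outranks a negative).
rank_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Centered rolling mean with shrinking (truncated) windows at the edges.
rolling_stat <- function(x, window, fun) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    fun(x[lo:hi])
  }, numeric(1))
}

stopf <- function(fmt, ..., class = "mbtraj_error") {
  abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) {
  warn(sprintf(fmt, ...))
}
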