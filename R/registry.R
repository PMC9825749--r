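# Regressor registry: every entry fits `time ~ features` and predicts on a
# numeric matrix. All stochastic fitters take an explicit seed and run
# single-threaded so repeated fits are identical.

registry_env <- new.env(parent = emptyenv())

register_regressor <- function(name, label, fit, predict) {
  registry_env[[name]] <- list(name = name, label = label, fit = fit,
                               predict = predict)
}

#' Available MMI regressors
#'
#' Names and descriptions of the built-in regressor registry. Any entry can
#' be used by [fit_mmi_model()], [compare_models()] and
#' [select_denominator()] (performance strategy).
#'
#' @return tibble: name, label.
#' @export
mb_regressors <- function() {
  entries <- mget(ls(registry_env), envir = registry_env)
  tibble::tibble(name = vapply(entries, `[[`, "", "name"),
                 label = vapply(entries, `[[`, "", "label")) |>
    dplyr::arrange(.data$name)
}

registry_get <- function(name) {
  entry <- registry_env[[name]]
  if (is.null(entry)) {
    stopf("unknown regressor '%s'; registry: %s", name,
          paste(sort(ls(registry_env)), collapse = ", "))
  }
  entry
}

registry_fit <- function(name, X, y, seed = 42) {
  entry <- registry_get(name)
  model <- entry$fit(X, y, seed)
  structure(list(name = name, model = model, feature_ids = colnames(X)),
            class = "mb_regressor_fit")
}

registry_predict <- function(fit, X) {
  X <- X[, fit$feature_ids, drop = FALSE]
  as.numeric(registry_get(fit$name)$predict(fit$model, X))
}

local({
  as_df <- function(X, y = NULL) {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(X))) # syntactic-name safe
    if (!is.null(y)) df$.y <- y
    df
  }

  register_regressor("dummy", "constant mean baseline",
    fit = function(X, y, seed) mean(y),
    predict = function(m, X) rep(m, nrow(X)))

  register_regressor("linear", "ordinary least squares",
    fit = function(X, y, seed) stats::lm(.y ~ ., data = as_df(X, y)),
    predict = function(m, X) {
      suppressWarnings(unname(stats::predict(m, newdata = as_df(X))))
    })

  glmnet_fit <- function(alpha) function(X, y, seed) {
    with_seed(seed, glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5))
  }
  glmnet_pred <- function(m, X) {
    as.numeric(stats::predict(m, newx = X, s = "lambda.min"))
  }
  register_regressor("ridge", "L2-regularized linear (glmnet, CV lambda)",
                     fit = glmnet_fit(0), predict = glmnet_pred)
  register_regressor("lasso", "L1-regularized linear (glmnet, CV lambda)",
                     fit = glmnet_fit(1), predict = glmnet_pred)

  register_regressor("knn", "k-nearest-neighbour mean (k = 5)",
    fit = function(X, y, seed) list(X = X, y = y, k = min(5, length(y))),
    predict = function(m, X) {
      apply(X, 1, function(r) {
        d <- sqrt(colSums((t(m$X) - r)^2))
        mean(m$y[order(d)[seq_len(m$k)]])
      })
    })

  register_regressor("tree", "single regression tree (rpart)",
    fit = function(X, y, seed) {
      with_seed(seed, rpart::rpart(.y ~ ., data = as_df(X, y), method = "anova"))
    },
    predict = function(m, X) unname(stats::predict(m, newdata = as_df(X))))

  register_regressor("bagged_trees", "bagged regression trees (ranger, mtry = p)",
    fit = function(X, y, seed) {
      ranger::ranger(x = as_df(X), y = y, num.trees = 100,
                     mtry = ncol(X), min.node.size = 5,
                     seed = seed, num.threads = 1)
    },
    predict = function(m, X) stats::predict(m, data = as_df(X),
                                            num.threads = 1)$predictions)

  register_regressor("random_forest", "random forest (ranger)",
    fit = function(X, y, seed) {
      ranger::ranger(x = as_df(X), y = y, num.trees = 200,
                     seed = seed, num.threads = 1)
    },
    predict = function(m, X) stats::predict(m, data = as_df(X),
                                            num.threads = 1)$predictions)

  register_regressor("boosted_trees", "gradient-boosted trees (xgboost)",
    fit = function(X, y, seed) {
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = 0.1,
                      max_depth = 3, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100)
    },
    predict = function(m, X) stats::predict(m, xgboost::xgb.DMatrix(X)))

  register_regressor("svr", "support-vector regression (radial kernel)",
    fit = function(X, y, seed) with_seed(seed, e1071::svm(X, y)),
    predict = function(m, X) unname(stats::predict(m, newdata = X)))
})
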