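#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for fitted mbtraj objects
#'
#' `tidy()` returns the per-unit results of an object (out-of-fold
#' predictions of an MMI model, per-candidate denominator scores,
#' per-group fits of a trajectory comparison, per-feature ranking of an
#' outlier explanation, per-feature changes of an intervention);
#' `glance()` returns a one-row model summary.
#'
#' @param x a fitted mbtraj object.
#' @param ... unused.
#' @return a tibble.
#' @name mbtraj-tidiers
NULL

#' @rdname mbtraj-tidiers
#' @export
tidy.mmi_model <- function(x, ...) x$oof

#' @rdname mbtraj-tidiers
#' @export
glance.mmi_model <- function(x, ...) {
  tibble::tibble(regressor = x$regressor,
                 n_train = length(x$training_samples),
                 n_features = length(x$feature_ids_used),
                 cv_r2 = x$cv_r2, level = x$level, interval = x$interval)
}

#' @rdname mbtraj-tidiers
#' @export
tidy.mb_denominator_report <- function(x, ...) {
  dplyr::mutate(x$scores, chosen = .data$feature_id == x$feature_id)
}

#' @rdname mbtraj-tidiers
#' @export
glance.mb_denominator_report <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, feature_id = x$feature_id,
                 ties_broken = x$ties_broken)
}

#' @rdname mbtraj-tidiers
#' @export
tidy.mb_trajectory_comparison <- function(x, ...) {
  if (x$method == "linear") {
    purrr::imap_dfr(x$per_group_fit, function(fit, g) {
      tibble::tibble(group = g, intercept = fit[["intercept"]],
                     slope = fit[["slope"]])
    })
  } else {
    purrr::imap_dfr(x$per_group_fit, function(fit, g) {
      dplyr::mutate(fit, group = g, .before = 1)
    })
  }
}

#' @rdname mbtraj-tidiers
#' @export
glance.mb_trajectory_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_permutations = x$n_permutations)
}

#' @rdname mbtraj-tidiers
#' @export
tidy.mb_outlier_explanation <- function(x, ...) x$ranking

#' @rdname mbtraj-tidiers
#' @export
glance.mb_outlier_explanation <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, auroc = x$auroc,
                 n_outliers = x$n_outliers, n_background = x$n_background)
}

#' @rdname mbtraj-tidiers
#' @export
tidy.mb_intervention <- function(x, ...) x$features_changed

#' @rdname mbtraj-tidiers
#' @export
glance.mb_intervention <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 n_features_changed = nrow(x$features_changed),
                 mmi_before = x$mmi_before, mmi_after = x$mmi_after,
                 residual_before = x$residual_before,
                 residual_after = x$residual_after,
                 returned_to_interval = x$returned_to_interval)
}

#' @rdname mbtraj-tidiers
#' @export
tidy.mb_shapley <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "attribution")
}
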