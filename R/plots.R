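#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_ribbon geom_col
#'   labs theme_minimal
NULL

#' Plot an MMI result against the reference trajectory
#'
#' Scatter of MMI versus time with the smooth trajectory and its interval
#' band; samples outside the band are highlighted.
#'
#' @param object an `mmi_result` from [predict_mmi()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mmi_result <- function(object, ...) {
  curve <- attr(object, "curve")
  grid <- seq(min(object$time), max(object$time), length.out = 200)
  band <- tibble::tibble(
    time = grid, fit = curve_eval(curve, grid),
    lo = curve_eval(curve, grid) -
      interval_halfwidth(curve, grid, kind = attr(object, "interval"),
                         level = attr(object, "level")),
    hi = curve_eval(curve, grid) +
      interval_halfwidth(curve, grid, kind = attr(object, "interval"),
                         level = attr(object, "level")))
  ggplot(object, aes(x = .data$time, y = .data$mmi)) +
    geom_ribbon(data = band, aes(x = .data$time, ymin = .data$lo,
                                 ymax = .data$hi),
                inherit.aes = FALSE, alpha = 0.2) +
    geom_line(data = band, aes(x = .data$time, y = .data$fit),
              inherit.aes = FALSE) +
    geom_point(aes(colour = .data$within_interval)) +
    labs(x = "time", y = "MMI (predicted time)",
         colour = "within interval") +
    theme_minimal()
}

#' Plot an anomaly report
#'
#' @param object an `mb_anomaly_report`.
#' @param ... unused.
#' @return a ggplot object of anomaly score against time.
#' @export
autoplot.mb_anomaly_report <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$score,
                     colour = .data$is_outlier)) +
    geom_point() +
    labs(x = "time", y = "anomaly score", colour = "outlier",
         title = unique(object$method)) +
    theme_minimal()
}

#' Plot a model leaderboard
#'
#' @param object an `mb_leaderboard` from [compare_models()].
#' @param ... unused.
#' @return a ggplot bar chart of grouped-CV mean R-squared per model.
#' @export
autoplot.mb_leaderboard <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$failed)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot(df, aes(x = .data$mean_r2, y = .data$model)) +
    geom_col() +
    labs(x = "grouped-CV mean R²", y = NULL) +
    theme_minimal()
}

#' Plot sampling statistics
#'
#' @param object an `mb_sampling_summary`.
#' @param ... unused.
#' @return a ggplot bar chart of samples per time bin.
#' @export
autoplot.mb_sampling_summary <- function(object, ...) {
  ggplot(object$per_timebin,
         aes(x = (.data$t_lo + .data$t_hi) / 2, y = .data$n_samples)) +
    geom_col(width = diff(range(object$per_timebin$t_lo)) /
               nrow(object$per_timebin) * 0.9) +
    labs(x = sprintf("time (%s)", object$time_unit), y = "samples") +
    theme_minimal()
}

#' Plot a 2-D embedding coloured by group
#'
#' @param embedding tibble from [embed_samples()].
#' @param ds the originating [mb_dataset()] (for group labels).
#' @return a ggplot object.
#' @export
plot_embedding <- function(embedding, ds) {
  df <- dplyr::left_join(embedding,
                         ds$metadata[c("sample_id", "group")],
                         by = "sample_id")
  ggplot(df, aes(x = .data$dim1, y = .data$dim2, colour = .data$group)) +
    geom_point() +
    labs(x = "dim 1", y = "dim 2") +
    theme_minimal()
}
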