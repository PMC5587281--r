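#' Plot a tri-axial recording
#'
#' @param object An [accel_recording()].
#' @param ... Unused.
#' @return A ggplot of the three axes over time (s).
#' @method autoplot accel_recording
#' @export
autoplot.accel_recording <- function(object, ...) {
  fs <- sampling_rate(object)
  df <- as_tibble(object)
  df$time_s <- (seq_len(nrow(df)) - 1) / fs
  long <- tidyr_longer(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$acceleration,
                                     colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time [s]", y = "Acceleration [g]", colour = "Axis") +
    ggplot2::theme_minimal()
}

# minimal wide->long for the three axes (avoids a tidyr dependency)
tidyr_longer <- function(df) {
  dplyr::bind_rows(lapply(c("x", "y", "z"), function(ax) {
    tibble(time_s = df$time_s, axis = ax, acceleration = df[[ax]])
  }))
}

#' Bland-Altman plot of a cross-validation result
#'
#' Held-out differences (predicted - measured, L/min) against the pairwise
#' means, with the bias and the 1.96 SD limits of agreement as horizontal
#' lines.
#'
#' @param object A `vo2_cv` from [loocv_vo2()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vo2_cv
#' @export
autoplot.vo2_cv <- function(object, ...) {
  df <- object$predictions
  df$mean_lmin <- (df$predicted + df$measured) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_lmin, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(
      x = "Mean of predicted and measured VO2peak [L/min]",
      y = "Predicted - measured [L/min]",
      title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f] L/min",
                      object$bias, object$loa_lower, object$loa_upper)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vo2_cv
#' @method autoplot vo2_fit
#' @export
autoplot.vo2_fit <- function(object, ...) {
  df <- tibble(measured = object$lm$model$vo2peak,
               fitted = stats::fitted(object$lm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$fitted)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Measured VO2peak [L/min]", y = "Fitted VO2peak [L/min]",
                  title = sprintf("r = %.3f, RMSE = %.3f L/min", object$r, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Bar plot of cross-validated error by fitness category
#'
#' @param cv A `vo2_cv` from [loocv_vo2()].
#' @param data The subject tibble the cross-validation used.
#' @return A ggplot of per-category RMSE_cv (L/min), labelled with the
#'   percentage of the category's mean measured VO2peak.
#' @export
plot_rmse_by_category <- function(cv, data) {
  df <- rmse_by_category(cv, data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitness_category, y = .data$rmse_cv)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f (%.0f%%)",
                                                    .data$rmse_cv, .data$rmse_cv_pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Fitness category [ml/min/kg]", y = "RMSE_cv [L/min]") +
    ggplot2::theme_minimal()
}
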