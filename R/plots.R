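#' Plot a cross-projection profile
#'
#' Draws the mean cross-projection as a function of the window end, with the
#' response duration and its 98% bounds marked when present.
#'
#' @param object A `crp_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crp_profile
#' @export
autoplot.crp_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$t2, y = .data$s_mean)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "window end t2 (s)",
      y = if (object$mode == "full") "mean cross-projection" else
        "mean cross-projection (uV.s)") +
    ggplot2::theme_minimal()
  if (!is.null(object$tau_R)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$tau_R_bounds,
                          linetype = "dotted", colour = "red") +
      ggplot2::annotate("point", x = object$tau_R, y = object$peak_value,
                        colour = "red", size = 2)
  }
  p
}

#' Plot trials, the canonical shape, or a full result
#'
#' `plot_trials()` overlays single trials with the across-trial mean;
#' `autoplot.crp_shape()` draws the canonical shape; `autoplot.crp_result()`
#' combines the profile, the scaled canonical shape and the per-trial
#' explained variance into one figure column-wise friendly for reports.
#'
#' @param epochs A [crp_epochs] object.
#' @param max_trials Cap on the number of trials drawn (default all).
#' @return A ggplot object.
#' @export
plot_trials <- function(epochs, max_trials = Inf) {
  stopifnot(inherits(epochs, "crp_epochs"))
  df <- tidy.crp_epochs(epochs)
  if (is.finite(max_trials)) df <- dplyr::filter(df, .data$trial <= max_trials)
  mean_df <- dplyr::summarise(dplyr::group_by(df, .data$time),
                              voltage = mean(.data$voltage), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$voltage,
                                   group = .data$trial)) +
    ggplot2::geom_line(alpha = 0.3, colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       colour = "black", linewidth = 0.6) +
    ggplot2::labs(x = "time from stimulus (s)", y = "voltage (uV)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trials
#' @param object A `crp_shape` or `crp_result`.
#' @param ... Unused.
#' @method autoplot crp_shape
#' @export
autoplot.crp_shape <- function(object, ...) {
  df <- tidy.crp_shape(object)
  xvar <- if ("time" %in% names(df)) "time" else "sample"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$C)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = if (xvar == "time") "time from stimulus (s)" else "sample",
                  y = "C(t) (unit norm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trials
#' @method autoplot crp_result
#' @export
autoplot.crp_result <- function(object, ...) {
  shape_df <- tidy.crp_shape(object$shape)
  if (!"time" %in% names(shape_df)) {
    shape_df$time <- object$config$t1 +
      (shape_df$sample - 1L) / object$config$fs
  }
  prof_df <- object$profile$profile
  scale_to <- max(abs(prof_df$s_mean))
  shape_df$scaled <- shape_df$C / max(abs(shape_df$C)) * scale_to
  ggplot2::ggplot() +
    ggplot2::geom_line(data = prof_df,
                       ggplot2::aes(x = .data$t2, y = .data$s_mean),
                       colour = "grey30", linewidth = 0.4) +
    ggplot2::geom_line(data = shape_df,
                       ggplot2::aes(x = .data$time, y = .data$scaled),
                       colour = "firebrick", linewidth = 0.5) +
    ggplot2::geom_vline(xintercept = object$tau_R, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "time / window end (s)",
                  y = "profile (uV.s) / scaled C(t)",
                  title = sprintf("tau_R = %.3g s, extraction p = %.2g",
                                  object$tau_R, object$extraction$p_value)) +
    ggplot2::theme_minimal()
}

#' Histogram of null-calibration p-values
#'
#' @param object A `crp_calibration`.
#' @param bins Number of histogram bins (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crp_calibration
#' @export
autoplot.crp_calibration <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tidy.crp_calibration(object),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            fill = "grey60", colour = "white") +
    ggplot2::geom_hline(yintercept = object$n_sets / bins,
                        linetype = "dashed") +
    ggplot2::labs(x = "extraction p-value", y = "count",
                  title = sprintf("%s-noise null, %d sets", object$noise,
                                  object$n_sets)) +
    ggplot2::theme_minimal()
}
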