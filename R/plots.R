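# ggplot2 visualisations mirroring the standard figures: saccade
# trajectories (displacement/velocity over the trial), dose-response
# curves, simulated dopamine traces and delay-period belief rasters.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a continuous trajectory
#'
#' Displacement from fixation and eye speed against time, with dashed
#' vertical lines at the 250 ms discrete-step boundaries.
#'
#' @param object An `ocu_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocu_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  df$displacement <- sqrt(df$x_deg^2 + df$y_deg^2)
  df$speed <- sqrt(df$vx_deg_s^2 + df$vy_deg_s^2)
  long <- tidyr::pivot_longer(
    df[, c("time_s", "displacement", "speed")], -"time_s",
    names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, c("displacement", "speed"),
                         c("displacement (deg)", "speed (deg/s)"))
  bounds <- df$time_s[c(diff(df$segment) != 0, FALSE)]
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' One panel per summary metric against the swept precision (log-scaled
#' where the grid is strictly positive).
#'
#' @param object A `dose_response` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response <- function(object, ...) {
  param <- attr(object, "parameter")
  long <- tidy.dose_response(object)
  long <- long[is.finite(long$estimate), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$estimate)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#253494") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = param, y = NULL) +
    ggplot2::theme_minimal()
  if (all(long$value > 0)) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a delay-period belief raster
#'
#' Rows are rate-coded populations (target location x represented time),
#' columns update epochs; lighter cells fire harder.
#'
#' @param object An `ocu_raster` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocu_raster <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), epoch = seq_len(ncol(m)))
  df$rate <- as.vector(m)[(df$epoch - 1L) * nrow(m) + df$row]
  df$label <- rownames(m)[df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, stats::reorder(.data$label, -.data$row),
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::labs(x = "update epoch", y = NULL, fill = "rate") +
    ggplot2::theme_minimal()
}

#' Plot simulated dopamine traces from a dopamine sweep
#'
#' @param sweep A [sweep_dopamine()] result (carries a `gamma_traces`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_gamma_traces <- function(sweep) {
  tr <- attr(sweep, "gamma_traces")
  if (is.null(tr)) stop("no gamma_traces attribute on this sweep", call. = FALSE)
  df <- tidyr::expand_grid(level = rownames(tr), iter = seq_len(ncol(tr)))
  df$gamma <- as.vector(t(tr))
  ggplot2::ggplot(df, ggplot2::aes(.data$iter, .data$gamma)) +
    ggplot2::geom_line(colour = "#e34a33") +
    ggplot2::facet_wrap(~level, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "update iteration (concatenated across steps)",
                  y = "expected precision (simulated dopamine)") +
    ggplot2::theme_minimal()
}

#' Plot a gamma recovery likelihood profile
#'
#' @param object A `gamma_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gamma_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$gamma, .data$loglik)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#253494") +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "candidate gamma", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
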