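# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trial into one row per discrete step
#'
#' @param x An `ocu_trial`.
#' @param ... Unused.
#' @return Tibble: `step`, `stage`, `action`, the four outcome columns and
#'   the attracting-point coordinates commanded for the step.
#' @export
tidy.ocu_trial <- function(x, ...) {
  Tt <- x$model$T
  acts <- c(NA_integer_, x$actions)[seq_len(Tt)]
  out <- x$outcome_tbl
  out$action <- c(.LOCATIONS[x$actions], NA_character_)[seq_len(Tt)]
  out$eta_x_deg <- x$eta_seq[seq_len(Tt), 1]
  out$eta_y_deg <- x$eta_seq[seq_len(Tt), 2]
  out$fixation_state <- .LOCATIONS[x$fixation_trace]
  out
}

#' One-row summary of a trial
#'
#' @param x An `ocu_trial`.
#' @param ... Unused.
#' @return Tibble with correctness, timing and kinematic summaries.
#' @export
glance.ocu_trial <- function(x, ...) {
  tibble::tibble(
    true_target = .TARGETS[x$true_target],
    correct = x$correct,
    premature = x$premature,
    persistence = persistence_index(x),
    peak_velocity = if (!is.null(x$metrics)) x$metrics$peak_velocity else NA_real_,
    amplitude = if (!is.null(x$metrics)) x$metrics$amplitude else NA_real_,
    endpoint_error = if (!is.null(x$metrics)) x$metrics$endpoint_error else NA_real_,
    n_saccades = if (!is.null(x$metrics)) x$metrics$n_saccades else NA_integer_,
    latency = if (!is.null(x$metrics)) x$metrics$latency else NA_real_
  )
}

#' Tidy a dose-response table into long format
#'
#' @param x A `dose_response` tibble.
#' @param ... Unused.
#' @return Long tibble: parameter `value`, `metric`, metric `estimate`.
#' @export
tidy.dose_response <- function(x, ...) {
  param <- attr(x, "parameter")
  df <- tibble::as_tibble(as.data.frame(x))
  df$value <- df[[param]]
  keep <- c("value", "accuracy", "peak_velocity", "amplitude",
            "inappropriate_rate", "overshoot_rate", "saccades_to_arrival",
            "persistence")
  df <- df[, intersect(keep, names(df))]
  tidyr::pivot_longer(df, -"value", names_to = "metric",
                      values_to = "estimate")
}

#' Tidy a gamma recovery fit (the likelihood profile)
#'
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @return Tibble: `gamma`, `loglik`.
#' @export
tidy.gamma_fit <- function(x, ...) x$profile

#' One-row summary of a gamma recovery fit
#'
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @return Tibble: `estimate`, `flat`, `n_trials`.
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, flat = x$flat, n_trials = x$n_trials)
}
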