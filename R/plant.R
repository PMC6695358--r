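# Continuous saccade generator: a second-order attractor filter whose
# flow towards the target competes with a stationarity (fixation) prior of
# precision pi_motor — the GABAergic nigro-collicular gain. The true eye
# follows the believed position through a fast first-order reflex.

#' Oculomotor plant parameters
#'
#' Defaults are calibrated so that at `pi_motor = 1` an 8 degree saccade is
#' near-critically damped with a peak velocity of order 1000 deg/s and
#' completes well within one 250 ms segment; `pi_motor` far below 1 gives an
#' underdamped (hypermetric, overshooting) saccade and far above 1 a slow,
#' hypometric, "broken" saccade spanning several segments.
#'
#' @param k Attractor stiffness (s^-2). The effective stiffness is
#'   `k * p_t / (p_t + pi_motor)`: fixation-prior precision shunts the
#'   pull towards the target.
#' @param p_t Precision of the target (descending) prior, weighing against
#'   `pi_motor` in the stiffness shunt (dimensionless).
#' @param lambda0 Baseline damping (s^-1).
#' @param c_lambda Damping contributed per unit `pi_motor` (s^-1): the
#'   fixation prior makes believed dynamics harder to update.
#' @param rho Reflex rate (s^-1) with which the true eye tracks the
#'   believed position.
#' @param dt Integration step (s).
#' @param segment_duration Duration of one discrete time step (s).
#' @param v_threshold Saccade detection threshold (deg/s).
#' @return A list of class `plant_params`.
#' @export
plant_params <- function(k = 3.2e5, p_t = 1, lambda0 = 250, c_lambda = 1080,
                         rho = 800, dt = 1e-3, segment_duration = 0.25,
                         v_threshold = 30) {
  stopifnot(k > 0, p_t > 0, lambda0 >= 0, c_lambda >= 0, rho > 0, dt > 0,
            segment_duration > 0, v_threshold > 0)
  structure(list(k = k, p_t = p_t, lambda0 = lambda0, c_lambda = c_lambda,
                 rho = rho, dt = dt, segment_duration = segment_duration,
                 v_threshold = v_threshold),
            class = "plant_params")
}

#' Continuous filter state
#'
#' @param position Numeric length-2 eye position (degrees), used for both
#'   the believed (`mu`) and true (`eye`) position at rest.
#' @return A list of class `filter_state` with fields `mu`, `mu_dot`,
#'   `eye`, `a` (motor signal) and `eps` (prediction errors).
#' @export
filter_state <- function(position = c(0, 0)) {
  stopifnot(length(position) == 2, all(is.finite(position)))
  structure(list(mu = position, mu_dot = c(0, 0), eye = position,
                 a = c(0, 0), eps = c(0, 0)),
            class = "filter_state")
}

#' Integrate one continuous segment
#'
#' Integrates the believed eye position `mu` as a second-order attractor
#' towards the target `eta`, with effective stiffness
#' `k_eff = k * p_t / (p_t + pi_motor)` and effective damping
#' `lambda_eff = lambda0 + c_lambda * pi_motor` (semi-implicit Euler, fixed
#' step). The true eye position relaxes towards `mu` at the reflex rate,
#' driven by the proprioceptive prediction error.
#'
#' @param state A [filter_state()].
#' @param eta Numeric length-2 attracting point (degrees).
#' @param pi_motor Positive motor fixation-prior precision.
#' @param duration Segment duration (s); must be an integer multiple of `dt`.
#' @param params A [plant_params()].
#' @param t0 Start time of the segment (s), used for the time stamps.
#' @param segment Integer segment label attached to the samples.
#' @return List with `trajectory` (a tibble: `time_s`, `x_deg`, `y_deg`,
#'   `vx_deg_s`, `vy_deg_s`, `segment`) and the final `state`.
#' @export
integrate_segment <- function(state, eta, pi_motor,
                              duration = NULL, params = plant_params(),
                              t0 = 0, segment = 1L) {
  stopifnot(inherits(state, "filter_state"), length(eta) == 2,
            is.numeric(pi_motor), pi_motor > 0)
  if (is.null(duration)) duration <- params$segment_duration
  dt <- params$dt
  n <- duration / dt
  if (abs(n - round(n)) > 1e-8)
    stop("duration must be an integer multiple of dt", call. = FALSE)
  n <- as.integer(round(n))
  k_eff <- params$k * params$p_t / (params$p_t + pi_motor)
  lambda_eff <- params$lambda0 + params$c_lambda * pi_motor
  if (k_eff * dt^2 >= 1)
    stop(sprintf("integration unstable: k_eff * dt^2 = %.3g >= 1; reduce dt",
                 k_eff * dt^2), call. = FALSE)
  mu <- state$mu; mu_dot <- state$mu_dot; eye <- state$eye
  pos <- matrix(NA_real_, n, 2)
  vel <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    eps_target <- eta - mu                       # error driving the attractor
    mu_dot <- (mu_dot + dt * k_eff * eps_target) / (1 + dt * lambda_eff)
    mu <- mu + dt * mu_dot
    eps_proprio <- mu - eye                      # drives the brainstem reflex
    a <- params$rho * eps_proprio
    eye_new <- (eye + dt * params$rho * mu) / (1 + dt * params$rho)
    vel[i, ] <- (eye_new - eye) / dt
    eye <- eye_new
    pos[i, ] <- eye
  }
  state$mu <- mu; state$mu_dot <- mu_dot; state$eye <- eye
  state$a <- if (n > 0) a else state$a
  state$eps <- if (n > 0) eps_proprio else state$eps
  traj <- tibble::tibble(
    time_s = t0 + dt * seq_len(n),
    x_deg = pos[, 1], y_deg = pos[, 2],
    vx_deg_s = vel[, 1], vy_deg_s = vel[, 2],
    segment = as.integer(segment)
  )
  class(traj) <- c("ocu_trajectory", class(traj))
  list(trajectory = traj, state = state)
}

# Stitch trajectory tibbles from consecutive segments.
.stitch_trajectories <- function(trajs) {
  out <- dplyr::bind_rows(trajs)
  class(out) <- c("ocu_trajectory", class(tibble::tibble()))
  out
}

#' Detect saccades and extract kinematic metrics
#'
#' Saccade events are maximal runs where eye speed exceeds `v_threshold`.
#' Peak velocity is the maximum speed over the whole trajectory, amplitude
#' the net displacement over the largest event, and (when a `target` is
#' given) overshoot is flagged when the displacement component along the
#' target direction exceeds the target distance by more than `overshoot_tol`
#' before settling.
#'
#' @param traj An `ocu_trajectory` tibble (see [integrate_segment()]).
#' @param v_threshold Detection threshold (deg/s).
#' @param target Optional length-2 target position (degrees) for
#'   endpoint-error and overshoot computation.
#' @param origin Length-2 start position used for the target direction.
#' @param overshoot_tol Degrees beyond the target distance that count as
#'   overshoot.
#' @return A one-row tibble of class `saccade_metrics`: `peak_velocity`,
#'   `amplitude`, `endpoint_error`, `n_saccades`, `overshoot`, `latency`.
#' @export
detect_saccades <- function(traj, v_threshold = 30, target = NULL,
                            origin = c(0, 0), overshoot_tol = 0.1) {
  stopifnot(nrow(traj) > 0)
  speed <- sqrt(traj$vx_deg_s^2 + traj$vy_deg_s^2)
  above <- speed > v_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values)
  n_sacc <- length(ev)
  peak <- max(speed, 0)
  amp <- 0
  if (n_sacc > 0) {
    amps <- vapply(ev, function(j) {
      i0 <- starts[j]; i1 <- ends[j]
      p0 <- if (i0 > 1) c(traj$x_deg[i0 - 1], traj$y_deg[i0 - 1]) else origin
      p1 <- c(traj$x_deg[i1], traj$y_deg[i1])
      sqrt(sum((p1 - p0)^2))
    }, numeric(1))
    amp <- max(amps)
  }
  latency <- if (n_sacc > 0) traj$time_s[starts[ev[1]]] - traj$time_s[1] else NA_real_
  endpoint <- c(traj$x_deg[nrow(traj)], traj$y_deg[nrow(traj)])
  endpoint_error <- if (!is.null(target)) sqrt(sum((endpoint - target)^2)) else NA_real_
  overshoot <- FALSE
  if (!is.null(target)) {
    dir <- target - origin
    dist <- sqrt(sum(dir^2))
    if (dist > 0) {
      u <- dir / dist
      proj <- (traj$x_deg - origin[1]) * u[1] + (traj$y_deg - origin[2]) * u[2]
      overshoot <- max(proj) > dist + overshoot_tol
    }
  }
  out <- tibble::tibble(
    peak_velocity = peak, amplitude = amp, endpoint_error = endpoint_error,
    n_saccades = n_sacc, overshoot = overshoot, latency = latency
  )
  class(out) <- c("saccade_metrics", class(out))
  out
}

# Number of suprathreshold events strictly before first arrival within
# `arrival_tol` of the target. Slow corrective components of broken saccades
# fall below the standard 30 deg/s criterion, so segmentation here uses a
# lower threshold.
.saccades_to_arrival <- function(traj, target, v_threshold = 10,
                                 arrival_tol = 1) {
  d <- sqrt((traj$x_deg - target[1])^2 + (traj$y_deg - target[2])^2)
  arrived <- which(d <= arrival_tol)
  upto <- if (length(arrived)) arrived[1] else nrow(traj)
  sub <- traj[seq_len(upto), , drop = FALSE]
  speed <- sqrt(sub$vx_deg_s^2 + sub$vy_deg_s^2)
  r <- rle(speed > v_threshold)
  sum(r$values)
}
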