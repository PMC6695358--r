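# End-to-end simulation of one trial: discrete perception and planning,
# policy-averaged descending predictions, continuous saccade execution and
# ascending proprioceptive evidence.

#' Run one trial of the delayed oculomotor task
#'
#' Loops over the discrete time steps. At each step the agent observes the
#' process outcomes (proprioception read off the plant endpoint), infers
#' hidden states under every remaining deep policy, evaluates expected free
#' energies, forms the policy posterior with iterated precision (simulated
#' dopamine) updates, samples an action, and sends the policy-averaged
#' posterior-predictive proprioceptive distribution for the next step to
#' the continuous plant as an attracting point. Each discrete step spans
#' one 250 ms continuous segment; believed velocity is re-anchored at
#' segment boundaries (the discrete sampling of saccadic vision).
#'
#' @param model An [build_model()] task model.
#' @param precisions A [precisions()] object.
#' @param true_target Target location: one of `"up"`, `"down"`, `"left"`,
#'   `"right"` or an integer 1-4.
#' @param seed Optional integer seed (reproducible action sampling).
#' @param plant Logical; integrate the continuous plant (default `TRUE`).
#'   With `FALSE`, proprioception is the identity map from the true
#'   fixation state and no trajectory is produced (exact for all discrete
#'   summaries; used by the large discrete-only sweeps).
#' @param plant_pars A [plant_params()].
#' @param obs_precision Ascending observation precision (deg^-2).
#' @param settle_segments Extra 250 ms segments integrated after the last
#'   step with the final attracting point held, so slow (broken) saccades
#'   can complete; kinematic sweeps use 2.
#' @param force_uniform_policy Logical; if `TRUE`, actions are sampled from
#'   a uniform policy posterior (the empirical chance-level oracle).
#' @param policy_cap Optional cap on enumerated policy depth.
#' @param n_precision_iter Precision-update iterations per step.
#' @return An object of class `ocu_trial`: actions, outcomes, `correct`,
#'   `premature`, belief history, per-step policy evaluations, the gamma
#'   (simulated dopamine) trace, the stitched trajectory and saccade
#'   metrics.
#' @export
#' @examples
#' m <- build_model()
#' tr <- run_trial(m, precisions(), "up", seed = 1)
#' tr$correct
run_trial <- function(model, precisions = ocupharm::precisions(),
                      true_target = "up", seed = NULL, plant = TRUE,
                      plant_pars = plant_params(), obs_precision = 4,
                      settle_segments = 0L, force_uniform_policy = FALSE,
                      policy_cap = NULL, n_precision_iter = 16L) {
  stopifnot(inherits(model, "ocu_task_model"))
  if (is.character(true_target)) true_target <- match(true_target, .TARGETS)
  if (is.na(true_target) || !(true_target %in% 1:4))
    stop("true_target must be one of up/down/left/right", call. = FALSE)
  with_seed(seed, .run_trial_impl(model, precisions, as.integer(true_target),
                                  plant, plant_pars, obs_precision,
                                  as.integer(settle_segments),
                                  force_uniform_policy, policy_cap,
                                  n_precision_iter))
}

.run_trial_impl <- function(model, prec, true_target, plant, plant_pars,
                            obs_precision, settle_segments, force_uniform,
                            policy_cap, n_precision_iter) {
  wm <- weight_model(model, prec)
  Tt <- model$T
  nf <- model$n_factors
  ns <- model$n_states
  locxy <- .loc_coords(model$locmap)
  target_xy <- locxy[true_target + 1L, ]

  obs <- matrix(NA_integer_, model$n_modalities, Tt)
  actions_taken <- integer(0)
  fix_state <- 1L
  premature <- FALSE
  fix_trace <- integer(Tt); fix_trace[1] <- fix_state

  pstate <- filter_state(locxy[1, ])
  trajs <- list()
  eta_seq <- matrix(NA_real_, Tt + settle_segments, 2)
  eta <- locxy[1, ]   # hold fixation during the first segment
  if (plant) {
    eta_seq[1, ] <- eta
    seg <- integrate_segment(pstate, eta, prec$pi_motor,
                             params = plant_pars, t0 = 0, segment = 1L)
    trajs[[1]] <- seg$trajectory
    pstate <- seg$state
  }

  bma_target <- array(NA_real_, dim = c(4L, Tt, Tt))  # state x tau x epoch
  policy_eval <- vector("list", Tt)
  beliefs_by_step <- vector("list", Tt)
  gamma_trace <- numeric(0)

  for (t in seq_len(Tt)) {
    po <- .process_outcomes(model, t, fix_state, true_target, premature)
    proprio <- if (plant) {
      .endpoint_outcome_index(pstate$eye, model$locmap, obs_precision)
    } else fix_state
    obs[, t] <- c(po[["cue"]], po[["colour"]], po[["feedback"]], proprio)

    depth <- Tt - t
    pol <- enumerate_policies(model$n_controls, depth, cap = policy_cap)
    P <- nrow(pol)
    acts <- if (Tt > 1) {
      cbind(matrix(rep(actions_taken, each = P), nrow = P),
            pol,
            matrix(1L, P, Tt - 1L - length(actions_taken) - ncol(pol)))
    } else matrix(integer(0), 1, 0)
    inf <- .infer_policies(wm, obs, acts)

    if (depth > 0) {
      G <- .efe_policies(wm, inf$q, future_tau = seq(t + 1L, Tt))
      ev <- .evaluate_policies(inf$F, G, beta_prior = prec$beta,
                               n_iter = n_precision_iter)
    } else {
      ev <- list(pi_posterior = 1, pi_prior = 1, beta = prec$beta,
                 gamma_trace = rep(1 / prec$beta, n_precision_iter),
                 G = 0, F = inf$F)
    }
    gamma_trace <- c(gamma_trace, ev$gamma_trace)

    pi_use <- if (force_uniform) rep(1 / P, P) else ev$pi_posterior
    # Bayesian-model-average beliefs (policy-weighted)
    qbma <- lapply(seq_len(nf), function(f) {
      matrix(inf$q[[f]], ns[f] * Tt, P) %*% pi_use |>
        matrix(ns[f], Tt)
    })
    bma_target[, , t] <- qbma[[2]]
    beliefs_by_step[[t]] <- list(q = inf$q, pi = pi_use, bma = qbma)

    action <- NA_integer_
    marginal <- NULL
    if (depth > 0) {
      sa <- sample_action(pi_use, pol, step = 1L, n_controls = model$n_controls)
      action <- sa$action
      marginal <- sa$marginal
      # descending message: posterior-predictive proprioception at t+1,
      # model-averaged over the policies consistent with the sampled action
      pi_cond <- .norm_vec(pi_use * (pol[, 1L] == action))
      qj <- .kr_list(lapply(seq_len(nf), function(f) {
        matrix(inf$q[[f]][, t + 1L, ], ns[f], P)
      })) %*% pi_cond
      o_pred <- drop(wm$A_flat[[4]] %*% qj)
      eta <- outcome_to_target(.norm_vec(o_pred), model$locmap)

      actions_taken <- c(actions_taken, action)
      fix_state <- action
      fix_trace[t + 1L] <- fix_state
      if (model$stage_kinds[t + 1L] %in% c("delay", "go") && fix_state != 1L)
        premature <- TRUE

      if (plant) {
        eta_seq[t + 1L, ] <- eta
        pstate$mu_dot <- c(0, 0); pstate$mu <- pstate$eye  # re-anchor
        seg <- integrate_segment(pstate, eta, prec$pi_motor,
                                 params = plant_pars,
                                 t0 = (t) * plant_pars$segment_duration,
                                 segment = t + 1L)
        trajs[[t + 1L]] <- seg$trajectory
        pstate <- seg$state
      }
    }
    policy_eval[[t]] <- list(policies = pol, F = inf$F, G = ev$G,
                             pi_posterior = ev$pi_posterior,
                             pi_prior = ev$pi_prior, beta = ev$beta,
                             gamma_trace = ev$gamma_trace,
                             action = action, action_marginal = marginal,
                             converged = inf$converged)
  }

  if (plant && settle_segments > 0) {
    for (sseg in seq_len(settle_segments)) {
      eta_seq[Tt + sseg, ] <- eta
      pstate$mu_dot <- c(0, 0); pstate$mu <- pstate$eye
      seg <- integrate_segment(pstate, eta, prec$pi_motor,
                               params = plant_pars,
                               t0 = (Tt + sseg - 1L) * plant_pars$segment_duration,
                               segment = Tt + sseg)
      trajs[[Tt + sseg]] <- seg$trajectory
      pstate <- seg$state
    }
  }

  trajectory <- if (plant) .stitch_trajectories(trajs) else NULL
  metrics <- segment_metrics <- NULL
  saccades_to_arrival <- NA_real_
  if (plant) {
    metrics <- detect_saccades(trajectory, plant_pars$v_threshold,
                               target = target_xy, origin = locxy[1, ])
    segment_metrics <- dplyr::bind_rows(lapply(split(trajectory, trajectory$segment),
      function(tr) detect_saccades(tr, plant_pars$v_threshold,
                                   target = target_xy, origin = locxy[1, ])))
    segment_metrics$segment <- sort(unique(trajectory$segment))
    saccades_to_arrival <- .saccades_to_arrival(trajectory, target_xy)
  }

  correct <- obs[3, Tt] == 2L
  saccade_steps <- which(diff(fix_trace) != 0)  # transition index

  structure(list(
    actions = actions_taken,
    outcomes = obs,
    outcome_tbl = .outcome_tibble(model, obs),
    correct = correct,
    premature = premature,
    fixation_trace = fix_trace,
    saccade_steps = saccade_steps,
    true_target = true_target,
    bma_target = bma_target,
    beliefs = beliefs_by_step,
    policy_eval = policy_eval,
    gamma_trace = gamma_trace,
    trajectory = trajectory,
    metrics = metrics,
    segment_metrics = segment_metrics,
    saccades_to_arrival = saccades_to_arrival,
    eta_seq = eta_seq,
    precisions = prec,
    model = model
  ), class = "ocu_trial")
}

.outcome_tibble <- function(model, obs) {
  on <- model$outcome_names
  tibble::tibble(
    step = seq_len(ncol(obs)),
    stage = model$stage_kinds,
    target_cue = on[[1]][obs[1, ]],
    cross_colour = on[[2]][obs[2, ]],
    feedback = on[[3]][obs[3, ]],
    proprioception = on[[4]][obs[4, ]]
  )
}

#' @export
print.ocu_trial <- function(x, ...) {
  cat("<ocu_trial> target =", .TARGETS[x$true_target],
      "| actions:", paste(.LOCATIONS[x$actions], collapse = " -> "),
      "|", if (x$correct) "correct" else "incorrect",
      if (x$premature) "(premature)" else "", "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  peak velocity %.1f deg/s, amplitude %.2f deg, %d saccade(s), endpoint error %.2f deg\n",
                x$metrics$peak_velocity, x$metrics$amplitude,
                x$metrics$n_saccades, x$metrics$endpoint_error))
  }
  invisible(x)
}

#' Delay-period belief raster from a trial
#'
#' Firing rates of rate-coded populations representing the remembered
#' target: one row per (target location x represented time), one column
#' per update epoch (discrete step). Entries are policy-averaged posterior
#' probabilities, so rows for a fixed represented time sum to 1 over the
#' four target locations in every column.
#'
#' @param trial An [run_trial()] result.
#' @return A matrix of class `ocu_raster` (`4 * T` rows, `T` columns).
#' @export
trial_raster <- function(trial) {
  stopifnot(inherits(trial, "ocu_trial"))
  Tt <- dim(trial$bma_target)[2]
  m <- matrix(aperm(trial$bma_target, c(1, 2, 3)), 4L * Tt, Tt)
  rownames(m) <- paste0(rep(.TARGETS, Tt), "@tau", rep(seq_len(Tt), each = 4))
  colnames(m) <- paste0("epoch", seq_len(Tt))
  class(m) <- c("ocu_raster", class(m))
  m
}

#' Persistence index of a trial
#'
#' The policy-averaged posterior probability assigned to the true target
#' at the final represented time, read from the last pre-feedback update
#' epoch (feedback itself would reveal the target and contaminate a memory
#' measure).
#'
#' @param trial An [run_trial()] result.
#' @return Scalar in `[0, 1]`.
#' @export
persistence_index <- function(trial) {
  stopifnot(inherits(trial, "ocu_trial"))
  Tt <- dim(trial$bma_target)[2]
  trial$bma_target[trial$true_target, Tt, Tt - 1L]
}

# Saccade events outside the go segment plus extra events within it.
# With the plant off, counts discrete fixation changes at wrong transitions.
.inappropriate_saccades <- function(trial) {
  Tt <- trial$model$T
  if (!is.null(trial$segment_metrics)) {
    sm <- trial$segment_metrics
    go_seg <- Tt  # the movement commanded at the go step lands in segment T
    extra_go <- max(0, sum(sm$n_saccades[sm$segment == go_seg]) - 1)
    outside <- sum(sm$n_saccades[sm$segment != go_seg & sm$segment <= Tt])
    outside + extra_go
  } else {
    moves <- which(diff(trial$fixation_trace) != 0)
    sum(moves != Tt - 1L)
  }
}
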