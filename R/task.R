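# The delayed (memory-guided) oculomotor task: a cue is flashed at one of
# four peripheral targets while the subject fixates; the cross turns red
# (delay; fixation must be maintained), then blue (go), and feedback scores
# whether the remembered target was acquired.

.LOCATIONS <- c("fixation", "up", "down", "left", "right")
.TARGETS <- c("up", "down", "left", "right")
.CUE_OUTCOMES <- c("up", "down", "left", "right", "none")
.COLOUR_OUTCOMES <- c("blue", "red")
.FEEDBACK_OUTCOMES <- c("null", "correct", "incorrect")

#' Build the delayed oculomotor task generative model
#'
#' Three hidden-state factors: the fixation location (5 states, the only
#' controllable factor — a saccade can move it to any location), the target
#' location (4 states, static in truth; the agent's model holds it stable
#' with probability `target_stability` per step, the handle by which the
#' transition precision `omega` acts), and the trial stage (cue, delay(s),
#' go, feedback; advancing deterministically). Four outcome modalities:
#' the target cue (visible only during the cue stage), the fixation-cross
#' colour (red only during the delay), feedback (non-null only once
#' informative: `incorrect` is emitted as soon as fixation leaves the cross
#' during delay/go, and `correct`/`incorrect` at the feedback stage), and
#' proprioception (an identity map from the fixation location). Preferences
#' assign `+c_pref` nats to `correct` and `-c_pref` to `incorrect`.
#'
#' Every conditional in the agent's likelihoods has finite base fidelity
#' `likelihood_fidelity`, so the likelihood precision `zeta` has a graded
#' effect (a 0/1 likelihood is invariant under precision exponents).
#'
#' @param eccentricity_deg Target eccentricity (degrees), `> 0`.
#' @param c_pref Preference magnitude (nats), `> 0`.
#' @param n_delay_steps Number of delay steps (default 1, giving the
#'   four-step trial: cue, delay, go, feedback).
#' @param likelihood_fidelity Base probability mass on the veridical
#'   outcome in each likelihood column, in (0.25, 1].
#' @param target_stability Agent's per-step probability that the target
#'   stays put, in (0.25, 1].
#' @return An `mdp_model` with task metadata (`locmap`, `stage_kinds`),
#'   class `c("ocu_task_model", "mdp_model")`.
#' @export
#' @examples
#' m <- build_model()
#' m$n_states     # 5, 4, 4
#' m$n_outcomes   # 5, 2, 3, 5
build_model <- function(eccentricity_deg = 8, c_pref = 4, n_delay_steps = 1,
                        likelihood_fidelity = 0.9, target_stability = 0.9) {
  if (!is.numeric(eccentricity_deg) || eccentricity_deg <= 0)
    stop("eccentricity_deg must be a positive number", call. = FALSE)
  if (!is.numeric(c_pref) || c_pref <= 0)
    stop("c_pref must be a positive number", call. = FALSE)
  if (!is.numeric(n_delay_steps) || n_delay_steps < 1 ||
      n_delay_steps != round(n_delay_steps))
    stop("n_delay_steps must be a positive integer", call. = FALSE)
  if (!is.numeric(likelihood_fidelity) || likelihood_fidelity <= 0.25 ||
      likelihood_fidelity > 1)
    stop("likelihood_fidelity must lie in (0.25, 1]", call. = FALSE)
  if (!is.numeric(target_stability) || target_stability <= 0.25 ||
      target_stability > 1)
    stop("target_stability must lie in (0.25, 1]", call. = FALSE)

  stage_kinds <- c("cue", rep("delay", n_delay_steps), "go", "feedback")
  Tt <- length(stage_kinds)
  ns <- c(5L, 4L, as.integer(Tt))   # fixation, target, stage
  f <- likelihood_fidelity

  soft_onehot <- function(n, i, fid = f) {
    p <- rep((1 - fid) / (n - 1), n)
    p[i] <- fid
    p
  }

  # A[[1]] target cue: depends on target and stage
  A1 <- array(0, dim = c(5L, ns))
  # A[[2]] cross colour: depends on stage
  A2 <- array(0, dim = c(2L, ns))
  # A[[3]] feedback: depends on fixation, target and stage
  A3 <- array(0, dim = c(3L, ns))
  # A[[4]] proprioception: identity from fixation
  A4 <- array(0, dim = c(5L, ns))
  for (fx in 1:5) for (tg in 1:4) for (st in seq_len(Tt)) {
    kind <- stage_kinds[st]
    A1[, fx, tg, st] <- if (kind == "cue") soft_onehot(5, tg) else soft_onehot(5, 5)
    A2[, fx, tg, st] <- if (kind == "delay") soft_onehot(2, 2) else soft_onehot(2, 1)
    A3[, fx, tg, st] <- switch(kind,
      cue = soft_onehot(3, 1),
      delay = ,
      go = if (fx != 1) soft_onehot(3, 3) else soft_onehot(3, 1),
      feedback = if (fx == tg + 1) soft_onehot(3, 2) else soft_onehot(3, 3)
    )
    A4[, fx, tg, st] <- soft_onehot(5, fx)
  }

  # B fixation: a saccade moves the eyes to the selected location
  B1 <- array(0, dim = c(5, 5, 5))
  for (u in 1:5) B1[u, , u] <- 1
  # B target: near-identity with base stability (agent's model)
  s <- target_stability
  B2 <- matrix((1 - s) / 3, 4, 4); diag(B2) <- s
  dim(B2) <- c(4, 4, 1)
  # B stage: deterministic advance, absorbing at the end
  B3 <- matrix(0, Tt, Tt)
  for (st in seq_len(Tt - 1)) B3[st + 1, st] <- 1
  B3[Tt, Tt] <- 1
  dim(B3) <- c(Tt, Tt, 1)

  C <- list(
    matrix(0, 5, Tt),
    matrix(0, 2, Tt),
    matrix(rep(c(0, c_pref, -c_pref), Tt), 3, Tt),
    matrix(0, 5, Tt)
  )
  D <- list(soft_onehot(5, 1, 1), rep(0.25, 4), soft_onehot(Tt, 1, 1))

  m <- mdp_model(
    A = list(A1, A2, A3, A4), B = list(B1, B2, B3), C = C, D = D, T = Tt,
    controllable = 1L,
    factor_names = c("fixation_location", "target_location", "trial_stage"),
    modality_names = c("target_cue", "cross_colour", "feedback", "proprioception"),
    state_names = list(.LOCATIONS, .TARGETS, stage_kinds),
    outcome_names = list(.CUE_OUTCOMES, .COLOUR_OUTCOMES, .FEEDBACK_OUTCOMES,
                         .LOCATIONS)
  )
  m$locmap <- location_map(eccentricity_deg)
  m$stage_kinds <- stage_kinds
  m$eccentricity_deg <- eccentricity_deg
  m$c_pref <- c_pref
  m$likelihood_fidelity <- likelihood_fidelity
  m$target_stability <- target_stability
  class(m) <- c("ocu_task_model", class(m))
  m
}

# Outcomes generated by the experimental apparatus (the generative process)
# for one time step, given true states. The process is deterministic and
# veridical; proprioception comes from the plant endpoint elsewhere.
.process_outcomes <- function(model, t, fix_state, target_state, premature) {
  kind <- model$stage_kinds[t]
  cue <- if (kind == "cue") target_state else 5L
  colour <- if (kind == "delay") 2L else 1L
  feedback <- switch(kind,
    cue = 1L,
    delay = ,
    go = if (fix_state != 1L) 3L else 1L,
    feedback = if (fix_state == target_state + 1L && !premature) 2L else 3L
  )
  c(cue = cue, colour = colour, feedback = feedback)
}
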