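# Discrete active-inference machinery: precision weighting, variational
# state inference under each policy, expected free energy, policy posteriors,
# precision (simulated dopamine) updates, and action sampling.

#' Construct a discrete generative model
#'
#' A generative model for a partially observed Markov decision process with
#' factorised hidden states. Outcomes in each modality are generated from the
#' joint hidden state through a likelihood array `A`; each hidden-state
#' factor evolves through its own transition array `B` (indexed by a control
#' state for the controllable factor); `C` holds log-preferences over
#' outcomes and `D` the initial state priors.
#'
#' @param A List (one per outcome modality) of arrays with dimensions
#'   `c(n_outcomes, n_states_factor1, n_states_factor2, ...)`. Columns
#'   (fixed joint state) must be probability distributions.
#' @param B List (one per hidden-state factor) of arrays with dimensions
#'   `c(n_states, n_states, n_controls)`; uncontrolled factors have a single
#'   control slice. Columns must be probability distributions.
#' @param C List (one per modality) of matrices `n_outcomes x T` of
#'   log-preferences (nats). Only relative differences matter.
#' @param D List (one per factor) of initial prior probability vectors.
#' @param T Integer number of discrete time steps in a trial.
#' @param controllable Integer index of the single controllable factor.
#' @param factor_names,modality_names Optional character names.
#' @param state_names,outcome_names Optional lists of per-level names.
#' @return An object of class `mdp_model`.
#' @export
mdp_model <- function(A, B, C, D, T, controllable = 1L,
                      factor_names = NULL, modality_names = NULL,
                      state_names = NULL, outcome_names = NULL) {
  stopifnot(is.list(A), is.list(B), is.list(C), is.list(D),
            length(B) == length(D), length(A) == length(C), T >= 1)
  ns <- vapply(D, length, integer(1))
  nf <- length(ns)
  no <- vapply(A, function(a) dim(as.array(a))[1], integer(1))
  A <- lapply(A, function(a) {
    a <- as.array(a)
    if (!identical(dim(a)[-1], as.integer(ns)) && !(nf == 1 && length(dim(a)) == 2 && dim(a)[2] == ns[1]))
      stop("A dimensions must be (n_outcomes, n_states per factor)", call. = FALSE)
    dim(a) <- c(dim(a)[1], ns)
    a
  })
  B <- lapply(seq_len(nf), function(f) {
    b <- as.array(B[[f]])
    if (length(dim(b)) == 2) dim(b) <- c(dim(b), 1L)
    if (dim(b)[1] != ns[f] || dim(b)[2] != ns[f])
      stop("B[[", f, "]] must be square in the factor's state count", call. = FALSE)
    b
  })
  for (m in seq_along(A)) {
    cols <- matrix(A[[m]], nrow = no[m])
    if (max(abs(colSums(cols) - 1)) > 1e-6)
      stop("A[[", m, "]] columns must sum to 1", call. = FALSE)
  }
  for (f in seq_len(nf)) {
    for (u in seq_len(dim(B[[f]])[3])) {
      if (max(abs(colSums(B[[f]][, , u]) - 1)) > 1e-6)
        stop("B[[", f, "]] columns must sum to 1", call. = FALSE)
    }
  }
  C <- lapply(seq_along(C), function(m) {
    cm <- C[[m]]
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = length(cm), ncol = T)
    if (any(!is.finite(cm))) stop("C must be finite", call. = FALSE)
    cm
  })
  D <- lapply(D, .norm_vec)
  structure(list(
    A = A, B = B, C = C, D = D, T = as.integer(T),
    n_states = as.integer(ns), n_outcomes = as.integer(no),
    n_factors = nf, n_modalities = length(A),
    controllable = as.integer(controllable),
    n_controls = dim(B[[controllable]])[3],
    factor_names = factor_names %||% paste0("factor", seq_len(nf)),
    modality_names = modality_names %||% paste0("modality", seq_along(A)),
    state_names = state_names, outcome_names = outcome_names
  ), class = "mdp_model")
}

#' @export
print.mdp_model <- function(x, ...) {
  cat("<mdp_model> ", x$n_factors, " factor(s) [",
      paste(x$n_states, collapse = ", "), "], ",
      x$n_modalities, " modalit(ies) [",
      paste(x$n_outcomes, collapse = ", "), "], T = ", x$T,
      ", controls = ", x$n_controls, "\n", sep = "")
  invisible(x)
}

#' Neuromodulatory precision parameters
#'
#' The four precisions swept in the pharmacology experiments, with defaults
#' that produce reliably correct delayed-saccade trials: `zeta` scales the
#' log-likelihood (acetylcholine; sensory confidence), `omega` scales
#' log-transitions (noradrenaline; confidence that hidden dynamics are
#' stable), `beta` is the inverse policy precision (`gamma = 1/beta`;
#' dopamine; confidence in plans), and `pi_motor` is the precision of the
#' motor fixation prior (GABAergic collicular gain on the saccade generator).
#'
#' @param zeta Likelihood precision, `>= 0` (dimensionless exponent).
#' @param omega Transition precision, `>= 0`.
#' @param beta Inverse policy precision, `> 0`.
#' @param pi_motor Motor fixation-prior precision, `> 0`.
#' @return An object of class `precisions`.
#' @export
#' @examples
#' precisions()                 # defaults
#' precisions(zeta = 0.5)      # cholinergic depletion
precisions <- function(zeta = 2, omega = 2, beta = 0.5, pi_motor = 1) {
  stopifnot(is.numeric(zeta), zeta >= 0, is.numeric(omega), omega >= 0,
            is.numeric(beta), beta > 0, is.numeric(pi_motor), pi_motor > 0)
  structure(list(zeta = zeta, omega = omega, beta = beta,
                 gamma = 1 / beta, pi_motor = pi_motor),
            class = "precisions")
}

#' @export
print.precisions <- function(x, ...) {
  cat(sprintf(
    "<precisions> zeta = %.4g, omega = %.4g, beta = %.4g (gamma = %.4g), pi_motor = %.4g\n",
    x$zeta, x$omega, x$beta, x$gamma, x$pi_motor))
  invisible(x)
}

#' Apply a precision exponent to a probability array
#'
#' Raises every conditional distribution (column over the first dimension)
#' to the power `precision` and renormalises: equivalently
#' `softmax(precision * log p)`. `precision = 1` is the identity,
#' `precision = 0` flattens every column to uniform, and large precisions
#' sharpen columns towards one-hot on the argmax. Zero entries are floored
#' at `1e-16` (then renormalised) before the logarithm.
#'
#' @param dist_array Matrix or array whose first dimension indexes the
#'   category (e.g. a likelihood or transition array); every column must be
#'   a probability distribution.
#' @param precision Non-negative scalar.
#' @return Array of the same shape with renormalised columns.
#' @export
#' @examples
#' apply_precision(matrix(c(0.8, 0.2), 2, 1), 2)  # ~ c(0.941, 0.059)
apply_precision <- function(dist_array, precision) {
  if (!is.numeric(precision) || length(precision) != 1 || precision < 0)
    stop("precision must be a non-negative scalar", call. = FALSE)
  a <- as.array(dist_array)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  m <- .floor_cols(m)
  out <- softmax(precision * log(m))
  dim(out) <- d
  dimnames(out) <- dimnames(dist_array)
  out
}

#' Precision-weight a generative model
#'
#' Applies the likelihood precision `zeta` to every modality's `A` array and
#' the transition precision `omega` to every factor's `B` array, and caches
#' the logarithms and contractions used by the inference engine.
#'
#' @param model An [mdp_model()].
#' @param precisions A [precisions()] object.
#' @return An `mdp_model` with weighted arrays and cached terms (class
#'   `c("weighted_mdp_model", "mdp_model")`).
#' @export
weight_model <- function(model, precisions = precisions()) {
  stopifnot(inherits(model, "mdp_model"))
  wm <- model
  wm$A <- lapply(model$A, apply_precision, precision = precisions$zeta)
  wm$B <- lapply(model$B, apply_precision, precision = precisions$omega)
  wm$precisions <- precisions
  wm <- .cache_model_terms(wm)
  class(wm) <- c("weighted_mdp_model", class(model))
  wm
}

# Precompute log-arrays, per-factor permuted likelihood slices, ambiguity
# vectors and preference log-targets.
.cache_model_terms <- function(wm) {
  nf <- wm$n_factors
  ns <- wm$n_states
  wm$A_flat <- lapply(wm$A, function(a) matrix(a, nrow = dim(a)[1]))
  wm$lnA_flat <- lapply(wm$A_flat, .ln)
  wm$lnB <- lapply(wm$B, .ln)
  wm$lnD <- lapply(wm$D, .ln)
  # H[[m]]: conditional outcome entropy per joint state (ambiguity source)
  wm$H <- lapply(seq_len(wm$n_modalities), function(m) {
    -colSums(wm$A_flat[[m]] * wm$lnA_flat[[m]])
  })
  # lnC[[m]]: log softmax of preferences per time step
  wm$lnC <- lapply(wm$C, function(cm) apply(cm, 2, function(v) v - log(sum(exp(v - max(v)))) - max(v)))
  # PA[[m]][[f]]: likelihood permuted so factor f's states come right after
  # the outcome dimension, flattened over the remaining factors (in
  # increasing original order).
  wm$PA <- lapply(seq_len(wm$n_modalities), function(m) {
    lapply(seq_len(nf), function(f) {
      others <- setdiff(seq_len(nf), f)
      pa <- aperm(array(wm$lnA_flat[[m]], dim = c(wm$n_outcomes[m], ns)),
                  c(1L, 1L + f, 1L + others))
      dim(pa) <- c(wm$n_outcomes[m], ns[f], prod(ns[others]))
      pa
    })
  })
  wm
}

#' Enumerate deep policies
#'
#' All control sequences for the controllable factor over `depth` remaining
#' transitions (full enumeration, optionally capped).
#'
#' @param n_controls Number of control states.
#' @param depth Number of remaining transitions.
#' @param cap Optional maximum enumerated depth; deeper horizons are
#'   truncated to `cap` transitions.
#' @return Integer matrix `n_policies x depth` of control indices.
#' @export
enumerate_policies <- function(n_controls, depth, cap = NULL) {
  if (!is.null(cap)) depth <- min(depth, cap)
  if (depth <= 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  g <- do.call(expand.grid, rep(list(seq_len(n_controls)), depth))
  as.matrix(unname(g))
}

# Internal vectorised inference over a set of policies.
#
# Structured variational scheme: each hidden-state factor keeps its full
# Markov-chain posterior (computed exactly by scaled forward-backward
# recursions given the other factors' marginals), and factors are coupled
# mean-field through the expected log-likelihood of the observed outcomes.
# For a single-factor model this is exact smoothing. The structured free
# energy has the closed form F = (nf - 1) * E_q[ln A terms] - sum_f ln Z_f
# and is non-increasing over factor updates.
#
# wm          weighted model (with cached terms)
# obs         integer matrix n_modalities x T; NA where unobserved
# actions     integer matrix n_policies x (T-1): full control sequence per
#             policy for the controllable factor (history + policy future)
# Returns list(q = list per factor of array (ns, T, P), F = vector P,
#              F_trace = matrix iter x P, converged, n_iter)
.infer_policies <- function(wm, obs, actions, max_iter = 16L, tol = 1e-4,
                            track_F = FALSE) {
  nf <- wm$n_factors; ns <- wm$n_states; Tt <- wm$T
  P <- nrow(actions)
  cf <- wm$controllable
  obs_tau <- which(colSums(!is.na(obs)) > 0)
  # beliefs as per-factor lists of per-time (ns x P) matrices
  ql <- lapply(seq_len(nf), function(f) {
    lapply(seq_len(Tt), function(tau) matrix(1 / ns[f], ns[f], P))
  })
  # policy groups by control value, per factor and transition
  groups <- lapply(seq_len(nf), function(f) {
    if (f == cf && dim(wm$B[[f]])[3] > 1 && Tt > 1) {
      lapply(seq_len(Tt - 1L), function(tr) split(seq_len(P), actions[, tr]))
    } else {
      rep(list(list("1" = seq_len(P))), max(Tt - 1L, 0L))
    }
  })
  gmm <- function(Bf, grp, qmat, transpose = FALSE) {
    if (length(grp) == 1L) {
      B <- Bf[, , as.integer(names(grp)[1])]
      return(if (transpose) crossprod(B, qmat) else B %*% qmat)
    }
    out <- matrix(0, if (transpose) ncol(Bf) else nrow(Bf), ncol(qmat))
    for (a in names(grp)) {
      idx <- grp[[a]]
      B <- Bf[, , as.integer(a)]
      out[, idx] <- if (transpose) crossprod(B, qmat[, idx, drop = FALSE]) else
        B %*% qmat[, idx, drop = FALSE]
    }
    out
  }
  # expected log-likelihood potentials for factor f at observed time tau
  psi_ln <- function(f, tau) {
    others <- setdiff(seq_len(nf), f)
    kr_other <- if (length(others)) {
      .kr_list(lapply(others, function(g) ql[[g]][[tau]]))
    } else matrix(1, 1, P)
    msg <- matrix(0, ns[f], P)
    for (m in seq_len(wm$n_modalities)) {
      o <- obs[m, tau]
      if (!is.na(o)) {
        V <- matrix(wm$PA[[m]][[f]][o, , ], ns[f])
        msg <- msg + V %*% kr_other
      }
    }
    msg
  }
  lnZ <- matrix(0, nf, P)
  F_trace <- matrix(NA_real_, nrow = 0, ncol = P)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    delta <- 0
    for (f in seq_len(nf)) {
      # scaled potentials exp(ln psi - colmax), accumulating the shift
      lnZf <- numeric(P)
      psis <- vector("list", Tt)
      for (tau in seq_len(Tt)) {
        if (tau %in% obs_tau) {
          lp <- psi_ln(f, tau)
          mx <- lp[cbind(max.col(t(lp), ties.method = "first"), seq_len(P))]
          psis[[tau]] <- exp(lp - rep(mx, each = ns[f]))
          lnZf <- lnZf + mx
        }
      }
      # forward pass with per-step rescaling
      alphas <- vector("list", Tt)
      a <- matrix(wm$D[[f]], ns[f], P)
      if (!is.null(psis[[1]])) a <- a * psis[[1]]
      cs <- colSums(a); lnZf <- lnZf + log(cs)
      a <- a * rep(1 / cs, each = ns[f])
      alphas[[1]] <- a
      if (Tt > 1) for (tau in 2:Tt) {
        a <- gmm(wm$B[[f]], groups[[f]][[tau - 1L]], a)
        if (!is.null(psis[[tau]])) a <- a * psis[[tau]]
        cs <- colSums(a); lnZf <- lnZf + log(cs)
        a <- a * rep(1 / cs, each = ns[f])
        alphas[[tau]] <- a
      }
      # backward pass; marginals alpha * beta-message
      b <- matrix(1, ns[f], P)
      for (tau in Tt:1) {
        qn <- alphas[[tau]] * b
        qn <- qn * rep(1 / colSums(qn), each = ns[f])
        delta <- max(delta, max(abs(qn - ql[[f]][[tau]])))
        ql[[f]][[tau]] <- qn
        if (tau > 1L) {
          bb <- if (!is.null(psis[[tau]])) b * psis[[tau]] else b
          b <- gmm(wm$B[[f]], groups[[f]][[tau - 1L]], bb, transpose = TRUE)
          b <- b * rep(1 / colSums(b), each = ns[f])
        }
      }
      lnZ[f, ] <- lnZf
    }
    if (track_F)
      F_trace <- rbind(F_trace, .free_energy(wm, ql, obs, lnZ, obs_tau))
    if (delta < tol) { converged <- TRUE; break }
  }
  Fv <- if (track_F) F_trace[nrow(F_trace), ] else
    .free_energy(wm, ql, obs, lnZ, obs_tau)
  # pack beliefs into (ns, T, P) arrays for consumers
  q <- lapply(seq_len(nf), function(f) {
    array(unlist(ql[[f]]), dim = c(ns[f], P, Tt)) |> aperm(c(1, 3, 2))
  })
  list(q = q, F = Fv, F_trace = if (track_F) F_trace else matrix(Fv, 1),
       converged = converged, n_iter = n_iter)
}

# Structured variational free energy per policy:
# F = (nf - 1) * E_q[sum of observed ln A terms] - sum_f ln Z_f.
# For one factor this is exactly minus the log marginal likelihood.
.free_energy <- function(wm, ql, obs, lnZ, obs_tau) {
  nf <- wm$n_factors
  P <- ncol(ql[[1]][[1]])
  L <- numeric(P)
  for (tau in obs_tau) {
    kr_all <- .kr_list(lapply(seq_len(nf), function(f) ql[[f]][[tau]]))
    for (m in seq_len(wm$n_modalities)) {
      o <- obs[m, tau]
      if (!is.na(o)) L <- L + drop(wm$lnA_flat[[m]][o, ] %*% kr_all)
    }
  }
  (nf - 1) * L - colSums(lnZ)
}

#' Infer hidden states under a single policy
#'
#' Fixed-point variational iteration given the outcomes observed so far and
#' a candidate policy. The posterior is structured: each hidden-state
#' factor's Markov chain is smoothed exactly (forward-backward) given the
#' other factors' marginals, and factors are iterated to convergence
#' (mean-field coupling through the likelihood). Single-factor models are
#' therefore solved exactly. The variational free energy `F` is
#' non-increasing across iterations; non-convergence within `max_iter` is
#' flagged and the last iterate returned.
#'
#' @param model A precision-weighted model from [weight_model()] (or an
#'   `mdp_model`, which is weighted with default precisions).
#' @param outcomes Integer matrix `n_modalities x T` of observed outcome
#'   indices, `NA` where unobserved; or a vector of length `n_modalities`
#'   for a single first observation.
#' @param policy Integer vector of control indices for the remaining
#'   transitions after the last observed step (may be empty).
#' @param actions Integer vector of control indices already taken (the
#'   history preceding/under the observed steps); defaults to none.
#' @param max_iter,tol Iteration controls.
#' @return List with `posterior` (per-factor `n_states x T` matrices), `F`
#'   (scalar), `F_trace`, `converged`, `n_iter`.
#' @export
infer_states <- function(model, outcomes, policy = integer(0),
                         actions = integer(0), max_iter = 16L, tol = 1e-4) {
  wm <- if (inherits(model, "weighted_mdp_model")) model else
    weight_model(model, precisions(zeta = 1, omega = 1))
  if (is.null(dim(outcomes))) {
    om <- matrix(NA_integer_, wm$n_modalities, wm$T)
    om[, 1] <- as.integer(outcomes)
    outcomes <- om
  }
  stopifnot(nrow(outcomes) == wm$n_modalities, ncol(outcomes) == wm$T)
  full <- c(as.integer(actions), as.integer(policy))
  if (length(full) < wm$T - 1L)
    full <- c(full, rep(1L, wm$T - 1L - length(full)))
  res <- .infer_policies(wm, outcomes, matrix(full[seq_len(wm$T - 1L)], nrow = 1),
                         max_iter = max_iter, tol = tol, track_F = TRUE)
  if (!res$converged)
    warning("state inference did not converge within max_iter; returning last iterate",
            call. = FALSE)
  list(posterior = lapply(res$q, function(a) matrix(a[, , 1], dim(a)[1], dim(a)[2])),
       F = unname(res$F[1]), F_trace = unname(res$F_trace[, 1]),
       converged = res$converged, n_iter = res$n_iter)
}

# Internal vectorised expected free energy over policies.
# future_tau: the time indices counted as "future" for this evaluation.
.efe_policies <- function(wm, q, future_tau) {
  nf <- wm$n_factors; ns <- wm$n_states
  P <- dim(q[[1]])[3]
  G <- numeric(P)
  for (tau in future_tau) {
    kr_all <- .kr_list(lapply(seq_len(nf), function(f) matrix(q[[f]][, tau, ], ns[f], P)))
    for (m in seq_len(wm$n_modalities)) {
      o_pred <- wm$A_flat[[m]] %*% kr_all
      risk <- colSums(o_pred * (.ln(o_pred) - wm$lnC[[m]][, tau]))
      ambiguity <- drop(wm$H[[m]] %*% kr_all)
      G <- G + risk + ambiguity
    }
  }
  G
}

#' Expected free energy of a policy
#'
#' Scores a policy by the sum, over its future time steps, of risk (the KL
#' divergence from the predicted outcome distribution to the preference
#' target `softmax(C)`) and ambiguity (the expected conditional entropy of
#' outcomes given states). Lower is better.
#'
#' @param model A precision-weighted model ([weight_model()]).
#' @param policy Integer vector of remaining control indices (used only to
#'   determine the horizon when `future_tau` is not given).
#' @param beliefs Per-factor `n_states x T` matrices of predicted state
#'   beliefs under the policy (e.g. from [infer_states()]).
#' @param future_tau Integer vector of time steps counted as future;
#'   defaults to the last `length(policy)` steps.
#' @return Scalar `G` (nats), with a `per_tau` attribute.
#' @export
expected_free_energy <- function(model, policy, beliefs, future_tau = NULL) {
  wm <- if (inherits(model, "weighted_mdp_model")) model else
    weight_model(model, precisions(zeta = 1, omega = 1))
  if (is.null(future_tau)) {
    h <- length(policy)
    future_tau <- if (h > 0) seq(wm$T - h + 1L, wm$T) else integer(0)
  }
  q <- lapply(seq_along(beliefs), function(f) {
    array(beliefs[[f]], dim = c(nrow(beliefs[[f]]), ncol(beliefs[[f]]), 1))
  })
  per_tau <- vapply(future_tau, function(tau) .efe_policies(wm, q, tau), numeric(1))
  structure(sum(per_tau), per_tau = stats::setNames(per_tau, future_tau))
}

#' Posterior over policies
#'
#' The policy prior is `softmax(-gamma * G)` — confidence in plans scaled by
#' the dopamine-like precision `gamma` — and the posterior additionally
#' accumulates the variational evidence `F` for each policy:
#' `softmax(-gamma * G - F)`. Both are invariant to adding a constant to `G`
#' or `F`.
#'
#' @param F Numeric vector of variational free energies per policy.
#' @param G Numeric vector of expected free energies per policy.
#' @param gamma Positive policy precision.
#' @return List with `prior` and `posterior` probability vectors.
#' @export
#' @examples
#' policy_posterior(F = c(0, 0), G = c(0, 1), gamma = 1)$posterior
policy_posterior <- function(F, G, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  stopifnot(length(F) == length(G), all(is.finite(F)), all(is.finite(G)))
  list(prior = softmax(-gamma * G),
       posterior = softmax(-gamma * G - F))
}

#' Update the policy precision (simulated dopamine)
#'
#' One Newton-style update of the inverse precision `beta` given the
#' divergence between the policy posterior and prior:
#' `beta_post = beta_prior + (pi_posterior - pi_prior) . G`, clipped below
#' at `clip`. When the posterior shifts mass towards low-`G` policies the
#' update lowers `beta`, i.e. raises `gamma = 1/beta` — a simulated
#' dopamine burst; shifts towards high-`G` policies produce a dip.
#'
#' @param beta_prior Positive scalar prior inverse precision.
#' @param G Expected free energies per policy.
#' @param pi_posterior,pi_prior Policy posterior and prior distributions.
#' @param clip Positive lower bound on `beta` (default `1/64`).
#' @return List with `beta`, `gamma`, and `clipped` (logical).
#' @export
update_precision <- function(beta_prior, G, pi_posterior, pi_prior,
                             clip = 1 / 64) {
  stopifnot(beta_prior > 0, length(pi_posterior) == length(G),
            length(pi_prior) == length(G))
  .assert_dist(pi_posterior, what = "pi_posterior")
  .assert_dist(pi_prior, what = "pi_prior")
  beta <- beta_prior + sum((pi_posterior - pi_prior) * G)
  clipped <- beta < clip
  if (clipped) beta <- clip
  list(beta = beta, gamma = 1 / beta, clipped = clipped)
}

# Iterated policy evaluation: alternate the posterior/prior softmaxes with
# damped beta updates until the fixed point, recording the gamma iterate
# (the simulated dopaminergic firing trace).
.evaluate_policies <- function(F, G, beta_prior, n_iter = 16L, clip = 1 / 64) {
  beta <- beta_prior
  gamma_trace <- numeric(n_iter)
  pi_post <- pi_prior <- NULL
  for (i in seq_len(n_iter)) {
    pp <- policy_posterior(F, G, 1 / beta)
    pi_prior <- pp$prior
    pi_post <- pp$posterior
    up <- update_precision(beta_prior, G, pi_post, pi_prior, clip = clip)
    beta <- beta + (up$beta - beta) / 2   # damped step towards the target
    gamma_trace[i] <- 1 / beta
  }
  list(pi_posterior = pi_post, pi_prior = pi_prior, beta = beta,
       gamma_trace = gamma_trace, G = G, F = F)
}

#' Sample an action from the policy posterior
#'
#' Marginalises the policy posterior over the next control (summing the
#' probability of all policies that share each next action) and samples one
#' action from the marginal. Ties in degenerate (one-hot) cases resolve to
#' the lowest index.
#'
#' @param pi_posterior Probability vector over policies.
#' @param policies Integer matrix `n_policies x depth` of control sequences
#'   (column `step` holds each policy's next action).
#' @param step Which column of `policies` is "next" (default 1).
#' @param n_controls Total number of control values (defaults to the max
#'   appearing in `policies`).
#' @param seed Optional RNG seed for reproducible sampling.
#' @return List with `action` (integer) and `marginal` (probability vector
#'   over controls).
#' @export
sample_action <- function(pi_posterior, policies, step = 1L,
                          n_controls = max(policies), seed = NULL) {
  .assert_dist(pi_posterior, what = "pi_posterior")
  stopifnot(nrow(policies) == length(pi_posterior), step <= ncol(policies))
  marginal <- vapply(seq_len(n_controls), function(u) {
    sum(pi_posterior[policies[, step] == u])
  }, numeric(1))
  marginal <- .norm_vec(marginal)
  action <- with_seed(seed, {
    sample.int(n_controls, 1L, prob = marginal)
  })
  list(action = as.integer(action), marginal = marginal)
}
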