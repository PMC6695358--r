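# The four drug experiments as precision sweeps, the omega x gamma
# interaction experiment, the empirical chance-level oracle and raster
# extraction.

# Run a batch of trials at fixed precisions; targets are balanced across
# the four locations and each trial draws its seed from a deterministic
# per-trial stream (so n_trials can grow without perturbing earlier trials).
.run_batch <- function(model, prec, n_trials, seed, plant = TRUE,
                       settle_segments = 0L, force_uniform = FALSE,
                       keep_trials = FALSE) {
  seeds <- trial_seeds(seed, n_trials)
  rows <- vector("list", n_trials)
  trials <- if (keep_trials) vector("list", n_trials) else NULL
  gtraces <- NULL
  for (i in seq_len(n_trials)) {
    tr <- run_trial(model, prec, true_target = ((i - 1L) %% 4L) + 1L,
                    seed = seeds[i], plant = plant,
                    settle_segments = settle_segments,
                    force_uniform_policy = force_uniform)
    rows[[i]] <- tibble::tibble(
      trial = i,
      correct = tr$correct,
      premature = tr$premature,
      persistence = persistence_index(tr),
      inappropriate = .inappropriate_saccades(tr),
      peak_velocity = if (plant) tr$metrics$peak_velocity else NA_real_,
      amplitude = if (plant) tr$metrics$amplitude else NA_real_,
      endpoint_error = if (plant) tr$metrics$endpoint_error else NA_real_,
      n_saccades = if (plant) tr$metrics$n_saccades else NA_integer_,
      overshoot = if (plant) tr$metrics$overshoot else NA,
      latency = if (plant) tr$metrics$latency else NA_real_,
      saccades_to_arrival = tr$saccades_to_arrival
    )
    if (is.null(gtraces)) gtraces <- matrix(0, n_trials, length(tr$gamma_trace))
    gtraces[i, ] <- tr$gamma_trace
    if (keep_trials) trials[[i]] <- tr
  }
  list(per_trial = dplyr::bind_rows(rows), gamma_traces = gtraces,
       trials = trials)
}

.summarise_batch <- function(batch, n_trials, seed) {
  pt <- batch$per_trial
  tibble::tibble(
    accuracy = mean(pt$correct),
    accuracy_se = stats::sd(pt$correct) / sqrt(n_trials),
    peak_velocity = mean(pt$peak_velocity),
    amplitude = mean(pt$amplitude),
    endpoint_error = mean(pt$endpoint_error),
    inappropriate_rate = mean(pt$inappropriate),
    overshoot_rate = mean(as.numeric(pt$overshoot)),
    saccades_to_arrival = mean(pt$saccades_to_arrival),
    persistence = mean(pt$persistence),
    n_trials = n_trials,
    seed = seed
  )
}

.dose_response <- function(rows, parameter, grid) {
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, !!parameter := grid, .before = 1)
  attr(out, "parameter") <- parameter
  class(out) <- c("dose_response", class(out))
  out
}

#' GABAergic sweep: motor fixation-prior precision
#'
#' Sweeps the motor prior precision `pi_motor` (benzodiazepine-like
#' collicular inhibition) with all other precisions at their defaults.
#' Expected phenomenology: peak velocity falls monotonically with
#' `pi_motor`; the lowest value overshoots (hypermetric, then corrected);
#' the highest gives slow hypometric saccades broken across segments.
#'
#' @param pi_grid Ascending positive grid of `pi_motor` values.
#' @param n_trials Trials per grid value.
#' @param seed Master seed.
#' @param settle_segments Extra segments so slow saccades can complete.
#' @return A `dose_response` tibble (one row per grid value).
#' @export
sweep_gaba <- function(pi_grid = c(0.25, 0.5, 1, 2, 4, 8), n_trials = 16,
                       seed = 1, settle_segments = 2L) {
  stopifnot(all(pi_grid > 0), !is.unsorted(pi_grid))
  model <- build_model()
  rows <- lapply(pi_grid, function(p) {
    b <- .run_batch(model, precisions(pi_motor = p), n_trials, seed,
                    plant = TRUE, settle_segments = settle_segments)
    .summarise_batch(b, n_trials, seed)
  })
  .dose_response(rows, "pi_motor", pi_grid)
}

#' Cholinergic sweep: likelihood precision
#'
#' Sweeps the likelihood precision `zeta`. Low `zeta` flattens the
#' posterior-predictive distribution over saccadic targets, so the
#' attracting point becomes a centre-weighted mixture: saccades shorten and
#' slow, and inappropriate saccades appear; peak velocity rises and
#' saturates as `zeta` grows.
#'
#' @param zeta_grid Ascending non-negative grid of `zeta` values.
#' @inheritParams sweep_gaba
#' @return A `dose_response` tibble.
#' @export
sweep_ach <- function(zeta_grid = c(0, 0.25, 0.5, 1, 2, 4), n_trials = 16,
                      seed = 1, settle_segments = 2L) {
  stopifnot(all(zeta_grid >= 0), !is.unsorted(zeta_grid))
  model <- build_model()
  rows <- lapply(zeta_grid, function(z) {
    b <- .run_batch(model, precisions(zeta = z), n_trials, seed,
                    plant = TRUE, settle_segments = settle_segments)
    .summarise_batch(b, n_trials, seed)
  })
  .dose_response(rows, "zeta", zeta_grid)
}

#' Dopaminergic sweep: policy precision
#'
#' Sweeps the prior policy precision `gamma = 1/beta`. As `gamma` tends to
#' zero all plans become equally probable and saccadic decisions are
#' random; accuracy rises monotonically with `gamma`, and at high `gamma`
#' the simulated dopamine trace is nearly flat (the correct policy is
#' inferred quickly and confidently).
#'
#' @param beta_grid Descending positive grid of `beta` values (so `gamma`
#'   ascends along rows).
#' @inheritParams sweep_gaba
#' @param plant Integrate the plant (default `FALSE`: the discrete
#'   summaries are exact without it and the sweep is large).
#' @return A `dose_response` tibble with a `gamma_traces` attribute: a
#'   matrix (grid value x trace sample) of trial-averaged simulated
#'   dopamine traces.
#' @export
sweep_dopamine <- function(beta_grid = c(64, 16, 4, 1, 0.25), n_trials = 200,
                           seed = 1, plant = FALSE) {
  stopifnot(all(beta_grid > 0), !is.unsorted(rev(beta_grid)))
  model <- build_model()
  traces <- NULL
  rows <- lapply(beta_grid, function(bb) {
    b <- .run_batch(model, precisions(beta = bb), n_trials, seed, plant = plant)
    traces <<- rbind(traces, colMeans(b$gamma_traces))
    .summarise_batch(b, n_trials, seed)
  })
  out <- .dose_response(rows, "beta", beta_grid)
  out <- tibble::add_column(out, gamma = 1 / beta_grid, .after = "beta")
  rownames(traces) <- paste0("gamma=", signif(1 / beta_grid, 3))
  attr(out, "gamma_traces") <- traces
  attr(out, "parameter") <- "gamma"
  out
}

#' Noradrenergic sweep: transition precision
#'
#' Sweeps the transition precision `omega`. Lower `omega` degrades the
#' propagation of the cue into later represented times — delay-period
#' persistence falls and the belief rasters lose structure — while deep
#' policies keep task performance largely intact over the default grid.
#'
#' @param omega_grid Ascending positive grid of `omega` values.
#' @inheritParams sweep_dopamine
#' @return A `dose_response` tibble with a `rasters` attribute: one
#'   representative-trial [trial_raster()] per grid value.
#' @export
sweep_noradrenaline <- function(omega_grid = c(0.75, 1.25, 2, 5), n_trials = 200,
                                seed = 1, plant = FALSE) {
  stopifnot(all(omega_grid > 0), !is.unsorted(omega_grid))
  model <- build_model()
  rasters <- list()
  rows <- lapply(omega_grid, function(w) {
    b <- .run_batch(model, precisions(omega = w), min(n_trials, n_trials), seed,
                    plant = plant, keep_trials = FALSE)
    rep_trial <- run_trial(model, precisions(omega = w), "up",
                           seed = trial_seeds(seed, 1), plant = FALSE)
    rasters[[paste0("omega=", w)]] <<- trial_raster(rep_trial)
    .summarise_batch(b, n_trials, seed)
  })
  out <- .dose_response(rows, "omega", omega_grid)
  attr(out, "rasters") <- rasters
  out
}

#' Empirical chance-level oracle
#'
#' Accuracy under a uniform policy posterior (actions sampled uniformly at
#' every step). Chance is computed empirically rather than assumed 1/4
#' because mistimed saccades also produce incorrect feedback.
#'
#' @param n_trials Number of oracle trials.
#' @param seed Master seed.
#' @param model Optional task model (defaults to [build_model()]).
#' @return A list with `accuracy`, `se`, `n_trials`.
#' @export
chance_level <- function(n_trials = 200, seed = 1, model = NULL) {
  model <- model %||% build_model()
  b <- .run_batch(model, precisions(), n_trials, seed, plant = FALSE,
                  force_uniform = TRUE)
  acc <- mean(b$per_trial$correct)
  list(accuracy = acc, se = stats::sd(b$per_trial$correct) / sqrt(n_trials),
       n_trials = n_trials)
}

#' Noradrenaline x dopamine interaction experiment
#'
#' Crosses transition precision `omega` with policy precision `gamma`
#' (via `beta`) and reports accuracy per cell with standard errors. The
#' directional hypothesis: under noradrenergic blockade (low `omega`),
#' task performance becomes more sensitive to dopamine depletion — the
#' accuracy drop from high to low `gamma` is larger at low `omega`.
#'
#' @param omega_grid,beta_grid Grids of length >= 2 (low and high arms at
#'   minimum).
#' @param n_trials Trials per cell.
#' @param seed Master seed.
#' @return A tibble of class `interaction_grid`: `omega`, `beta`, `gamma`,
#'   `accuracy`, `accuracy_se`, `n_trials`.
#' @export
interaction_grid <- function(omega_grid = c(0.6, 4), beta_grid = c(1, 0.5),
                             n_trials = 500, seed = 1) {
  stopifnot(length(omega_grid) >= 2, length(beta_grid) >= 2,
            all(omega_grid > 0), all(beta_grid > 0))
  model <- build_model()
  cells <- tidyr::expand_grid(omega = omega_grid, beta = beta_grid)
  res <- purrr::pmap_dfr(cells, function(omega, beta) {
    b <- .run_batch(model, precisions(omega = omega, beta = beta),
                    n_trials, seed, plant = FALSE)
    tibble::tibble(
      omega = omega, beta = beta, gamma = 1 / beta,
      accuracy = mean(b$per_trial$correct),
      accuracy_se = stats::sd(b$per_trial$correct) / sqrt(n_trials),
      n_trials = n_trials
    )
  })
  class(res) <- c("interaction_grid", class(res))
  res
}

#' Interaction effect (difference in differences)
#'
#' Accuracy loss from gamma depletion at the lowest omega minus the same
#' loss at the highest omega; positive values support the hypothesis that
#' noradrenergic blockade increases sensitivity to dopamine depletion.
#'
#' @param grid An [interaction_grid()] result.
#' @return List with `effect`, `se` and the per-arm drops.
#' @export
interaction_effect <- function(grid) {
  stopifnot(inherits(grid, "interaction_grid"))
  lo_w <- min(grid$omega); hi_w <- max(grid$omega)
  lo_g <- min(grid$gamma); hi_g <- max(grid$gamma)
  cell <- function(w, g) grid[grid$omega == w & grid$gamma == g, ]
  drop_low <- cell(lo_w, hi_g)$accuracy - cell(lo_w, lo_g)$accuracy
  drop_high <- cell(hi_w, hi_g)$accuracy - cell(hi_w, lo_g)$accuracy
  se <- sqrt(sum(vapply(
    list(cell(lo_w, hi_g), cell(lo_w, lo_g), cell(hi_w, hi_g), cell(hi_w, lo_g)),
    function(r) r$accuracy_se^2, numeric(1))))
  list(effect = drop_low - drop_high, se = se,
       drop_low_omega = drop_low, drop_high_omega = drop_high)
}
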