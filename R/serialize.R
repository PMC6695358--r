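# Serialization: lossless JSON round-trips for generative models, CSV
# output for trajectories, dose-response tables and rasters, JSON records
# for trial results and fits. CSV floats are written at 9 significant
# digits so identical runs produce byte-identical files.

.sig9 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 9) else x
}

.write_csv9 <- function(df, path) {
  df <- as.data.frame(lapply(df, .sig9))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.pack_array <- function(a) list(dim = dim(as.array(a)), values = as.vector(a))
.unpack_array <- function(x) array(unlist(x$values), dim = unlist(x$dim))

#' Serialize a generative model to JSON
#'
#' Writes named factors and modalities, the nested `A`/`B`/`C`/`D` arrays
#' and the (optional) policy list. The round trip through
#' [read_model_json()] is lossless to better than `1e-12`.
#'
#' @param model An `mdp_model`.
#' @param path Output path.
#' @param policies Optional policy matrix to include.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, policies = NULL) {
  stopifnot(inherits(model, "mdp_model"))
  payload <- list(
    factor_names = model$factor_names,
    modality_names = model$modality_names,
    n_states = model$n_states,
    n_outcomes = model$n_outcomes,
    T = model$T,
    controllable = model$controllable,
    A = lapply(model$A, .pack_array),
    B = lapply(model$B, .pack_array),
    C = lapply(model$C, .pack_array),
    D = model$D,
    state_names = model$state_names,
    outcome_names = model$outcome_names,
    policies = if (!is.null(policies)) .pack_array(policies) else NULL,
    task = if (inherits(model, "ocu_task_model")) list(
      eccentricity_deg = model$eccentricity_deg,
      c_pref = model$c_pref,
      stage_kinds = model$stage_kinds,
      likelihood_fidelity = model$likelihood_fidelity,
      target_stability = model$target_stability
    ) else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a generative model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return An `mdp_model` (an `ocu_task_model` when task metadata is
#'   present).
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  m <- mdp_model(
    A = lapply(p$A, .unpack_array),
    B = lapply(p$B, .unpack_array),
    C = lapply(p$C, function(x) {
      a <- .unpack_array(x); matrix(a, nrow = dim(a)[1])
    }),
    D = lapply(p$D, as.numeric),
    T = p$T, controllable = p$controllable,
    factor_names = p$factor_names, modality_names = p$modality_names,
    state_names = p$state_names, outcome_names = p$outcome_names
  )
  if (!is.null(p$task)) {
    m$locmap <- location_map(p$task$eccentricity_deg)
    m$stage_kinds <- unlist(p$task$stage_kinds)
    m$eccentricity_deg <- p$task$eccentricity_deg
    m$c_pref <- p$task$c_pref
    m$likelihood_fidelity <- p$task$likelihood_fidelity
    m$target_stability <- p$task$target_stability
    class(m) <- c("ocu_task_model", class(m))
  }
  m
}

#' Write a trajectory to CSV
#'
#' Columns `time_s`, `x_deg`, `y_deg`, `vx_deg_s`, `vy_deg_s`,
#' `segment_index`, floats at 9 significant digits.
#'
#' @param traj An `ocu_trajectory` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[names(df) == "segment"] <- "segment_index"
  .write_csv9(df, path)
}

#' Write a dose-response table to CSV
#'
#' @param dr A `dose_response` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(dr, path) {
  .write_csv9(as.data.frame(dr), path)
}

#' Write a belief raster to CSV (with JSON metadata)
#'
#' The matrix goes to `path`; row/column labels and the trial context go
#' to `paste0(path, ".json")`.
#'
#' @param raster An `ocu_raster` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  m <- unclass(raster)
  .write_csv9(as.data.frame(m), path)
  jsonlite::write_json(list(rows = rownames(m), cols = colnames(m)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a trial result to JSON
#'
#' Actions, outcomes, correctness, saccade metrics and the simulated
#' dopamine trace (the trajectory goes to CSV via
#' [write_trajectory_csv()]).
#'
#' @param trial An `ocu_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  payload <- list(
    true_target = .TARGETS[trial$true_target],
    actions = .LOCATIONS[trial$actions],
    correct = trial$correct,
    premature = trial$premature,
    outcomes = trial$outcome_tbl,
    metrics = if (!is.null(trial$metrics)) as.list(trial$metrics) else NULL,
    saccades_to_arrival = trial$saccades_to_arrival,
    persistence_index = persistence_index(trial),
    gamma_trace = trial$gamma_trace,
    precisions = unclass(trial$precisions)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
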