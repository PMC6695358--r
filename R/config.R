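# Run configuration: schema-validated YAML/JSON with defaults, rejected
# unknown keys, and a resolved provenance copy written next to outputs.

#' Default run configuration
#'
#' @return Nested list with blocks `task`, `plant`, `precisions`, `sweep`
#'   and top-level `n_trials`, `seed`, `outdir`, `plot`.
#' @export
default_config <- function() {
  list(
    task = list(eccentricity_deg = 8, c_pref = 4, n_delay_steps = 1,
                likelihood_fidelity = 0.9, target_stability = 0.9),
    plant = list(k = 3.2e5, p_t = 1, lambda0 = 250, c_lambda = 1080,
                 rho = 800, dt = 1e-3, segment_duration = 0.25,
                 v_threshold = 30),
    precisions = list(zeta = 2, omega = 2, beta = 0.5, pi_motor = 1),
    sweep = list(pi_grid = c(0.25, 0.5, 1, 2, 4, 8),
                 zeta_grid = c(0, 0.25, 0.5, 1, 2, 4),
                 beta_grid = c(64, 16, 4, 1, 0.25),
                 omega_grid = c(0.75, 1.25, 2, 5)),
    n_trials = 16,
    seed = 1,
    outdir = "ocupharm-output",
    plot = FALSE
  )
}

.check_domain <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("config key '%s' invalid: %s", key, msg),
                  call. = FALSE)
  }
  chk(cfg$task$eccentricity_deg > 0, "task.eccentricity_deg", "must be > 0")
  chk(cfg$task$c_pref > 0, "task.c_pref", "must be > 0")
  chk(cfg$task$n_delay_steps >= 1, "task.n_delay_steps", "must be >= 1")
  chk(cfg$task$likelihood_fidelity > 0.25 && cfg$task$likelihood_fidelity <= 1,
      "task.likelihood_fidelity", "must lie in (0.25, 1]")
  chk(cfg$plant$dt > 0, "plant.dt", "must be > 0")
  chk(cfg$plant$k > 0, "plant.k", "must be > 0")
  chk(cfg$precisions$zeta >= 0, "precisions.zeta", "must be >= 0")
  chk(cfg$precisions$omega >= 0, "precisions.omega", "must be >= 0")
  chk(cfg$precisions$beta > 0, "precisions.beta", "must be > 0")
  chk(cfg$precisions$pi_motor > 0, "precisions.pi_motor", "must be > 0")
  chk(cfg$n_trials >= 1, "n_trials", "must be >= 1")
  invisible(cfg)
}

.merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s'", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key '%s' must be a block", full), call. = FALSE)
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (same schema), fills defaults, rejects unknown keys
#' by name and checks parameter domains. An empty or missing file yields
#' the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for
#'   defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(default_config(), user)
  .check_domain(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration to YAML
#'
#' `load_config(dump_config(cfg, path))` round-trips the configuration.
#'
#' @param cfg A configuration list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Small polynomial rolling hash of the canonical serialized config, for
# provenance logs.
.config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in as.integer(charToRaw(txt))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
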