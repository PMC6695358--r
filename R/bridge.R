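# Hybrid bridge between the discrete decision level and the continuous
# plant: descending, posterior-predictive location outcomes become a single
# attracting point (a Bayesian model average of coordinates); ascending,
# realized trajectory endpoints become discrete proprioceptive evidence.

#' Task location map
#'
#' Coordinates of the discrete locations: the central fixation cross and
#' four peripheral targets at the cardinal directions. Peripheral targets
#' are symmetric about fixation, so a uniform mixture over them maps back
#' to the fixation point.
#'
#' @param eccentricity_deg Eccentricity of the peripheral targets (degrees).
#' @param fixation Length-2 coordinates of the fixation cross.
#' @return A tibble of class `location_map` with columns `name`, `x_deg`,
#'   `y_deg`.
#' @export
#' @examples
#' location_map(8)
location_map <- function(eccentricity_deg = 8, fixation = c(0, 0)) {
  stopifnot(is.numeric(eccentricity_deg), eccentricity_deg > 0,
            length(fixation) == 2)
  e <- eccentricity_deg
  out <- tibble::tibble(
    name = c("fixation", "up", "down", "left", "right"),
    x_deg = fixation[1] + c(0, 0, 0, -e, e),
    y_deg = fixation[2] + c(0, e, -e, 0, 0)
  )
  class(out) <- c("location_map", class(out))
  out
}

.loc_coords <- function(locmap) {
  as.matrix(locmap[, c("x_deg", "y_deg")])
}

#' Descending message: predictive outcomes to an attracting point
#'
#' The continuous saccade generator is driven by a single equilibrium
#' (attracting) point: the expectation of the discrete location coordinates
#' under the posterior-predictive distribution. With an imprecise
#' predictive distribution the anticipated location is a mixture of all
#' possible locations weighted by their probability, pulling saccades
#' towards the centre; as the predictive sharpens the point moves onto a
#' specific target.
#'
#' @param predictive Probability vector over locations (same order as
#'   `locmap`).
#' @param locmap A [location_map()].
#' @return Numeric length-2 attracting point (degrees).
#' @export
#' @examples
#' lm <- location_map(8)
#' outcome_to_target(c(0, 1, 0, 0, 0), lm)        # exactly "up"
#' outcome_to_target(c(0.5, 0.5, 0, 0, 0), lm)    # halfway to "up"
outcome_to_target <- function(predictive, locmap) {
  stopifnot(length(predictive) == nrow(locmap))
  .assert_dist(predictive, tol = 1e-6, what = "predictive distribution")
  unname(drop(crossprod(.loc_coords(locmap), predictive)))
}

#' Ascending message: trajectory endpoint to discrete proprioception
#'
#' Converts a realized eye position into a categorical distribution over
#' the discrete proprioceptive outcomes: a softmax over locations of
#' `-0.5 * obs_precision * squared distance`. At high observation precision
#' this recovers the identity mapping (the nearest location); as
#' `obs_precision` tends to zero it flattens to uniform.
#'
#' @param endpoint Numeric length-2 eye position (degrees).
#' @param locmap A [location_map()].
#' @param obs_precision Positive observation precision (deg^-2).
#' @return Probability vector over locations (named by location).
#' @export
endpoint_to_outcome <- function(endpoint, locmap, obs_precision = 4) {
  stopifnot(length(endpoint) == 2, is.numeric(obs_precision),
            obs_precision > 0)
  xy <- .loc_coords(locmap)
  d2 <- (xy[, 1] - endpoint[1])^2 + (xy[, 2] - endpoint[2])^2
  stats::setNames(softmax(-0.5 * obs_precision * d2), locmap$name)
}

# Sampled (argmax at sharp precisions) discrete proprioceptive outcome.
# Ties resolve to the lowest index.
.endpoint_outcome_index <- function(endpoint, locmap, obs_precision = 4) {
  which.max(endpoint_to_outcome(endpoint, locmap, obs_precision))
}
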