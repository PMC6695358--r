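# Continuous saccade generator: attractor dynamics, stability, metric
# extraction and the pi_motor (GABA) phenomenology.

test_that("a target at the current position leaves the eye stationary", {
  st <- filter_state(c(0, 0))
  out <- integrate_segment(st, eta = c(0, 0), pi_motor = 1)
  mx <- detect_saccades(out$trajectory)
  expect_equal(mx$peak_velocity, 0, tolerance = 1e-9)
  expect_equal(mx$n_saccades, 0L)
  expect_equal(out$state$eye, c(0, 0), tolerance = 1e-9)
})

test_that("a default saccade to 8 degrees is single, accurate and smooth", {
  st <- filter_state(c(0, 0))
  out <- integrate_segment(st, eta = c(0, 8), pi_motor = 1)
  mx <- detect_saccades(out$trajectory, target = c(0, 8))
  expect_equal(mx$n_saccades, 1L)
  expect_false(mx$overshoot)
  expect_lt(mx$endpoint_error, 0.1)
  expect_gt(mx$peak_velocity, 300)
})

test_that("low pi_motor overshoots with a higher peak; high is slow/hypometric", {
  run_at <- function(p) {
    out <- integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = p)
    detect_saccades(out$trajectory, target = c(0, 8))
  }
  lo <- run_at(0.25); mid <- run_at(1); hi <- run_at(8)
  expect_true(lo$overshoot)
  expect_gt(lo$peak_velocity, mid$peak_velocity)
  expect_false(mid$overshoot)
  expect_lt(hi$peak_velocity, mid$peak_velocity)
  expect_gt(hi$endpoint_error, mid$endpoint_error)
})

test_that("peak velocity decreases strictly along the pi_motor grid", {
  peaks <- vapply(c(0.25, 0.5, 1, 2, 4, 8), function(p) {
    out <- integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = p)
    detect_saccades(out$trajectory)$peak_velocity
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("halving dt changes the endpoint by less than 0.1 degree", {
  for (p in c(0.25, 1, 8)) {
    e1 <- integrate_segment(filter_state(c(0, 0)), c(0, 8), p)$state$eye
    e2 <- integrate_segment(filter_state(c(0, 0)), c(0, 8), p,
                            params = plant_params(dt = 5e-4))$state$eye
    expect_lt(sqrt(sum((e1 - e2)^2)), 0.1)
  }
})

test_that("the velocity trace integrates back to the net displacement", {
  out <- integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = 1)
  tr <- out$trajectory
  dt <- diff(tr$time_s[1:2])
  # trapezoid over the trace including the initial rest sample
  v <- c(0, tr$vy_deg_s)
  net <- tr$y_deg[nrow(tr)]
  integ <- sum((v[-1] + v[-length(v)]) / 2) * dt
  expect_lt(abs(integ - net) / abs(net), 0.01)
})

test_that("amplitude stays physiological at default parameters", {
  out <- integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = 1)
  mx <- detect_saccades(out$trajectory, target = c(0, 8))
  expect_lte(mx$amplitude, 1.5 * 8)
  lo <- integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = 0.25)
  expect_true(detect_saccades(lo$trajectory, target = c(0, 8))$overshoot)
})

test_that("detect_saccades handles constructed velocity traces", {
  # all-zero velocity
  flat <- tibble::tibble(time_s = seq(0, 0.1, by = 1e-3),
                         x_deg = 0, y_deg = 0, vx_deg_s = 0, vy_deg_s = 0,
                         segment = 1L)
  m0 <- detect_saccades(flat)
  expect_equal(m0$n_saccades, 0L)
  expect_equal(m0$peak_velocity, 0)
  # one bell-shaped pulse crossing threshold once
  tt <- seq(0, 0.1, by = 1e-3)
  v <- 200 * exp(-((tt - 0.05) / 0.01)^2)
  pulse <- tibble::tibble(time_s = tt, x_deg = cumsum(v) * 1e-3, y_deg = 0,
                          vx_deg_s = v, vy_deg_s = 0, segment = 1L)
  m1 <- detect_saccades(pulse)
  expect_equal(m1$n_saccades, 1L)
  expect_equal(m1$peak_velocity, max(v))
})

test_that("an unstable step size is rejected with a clear error", {
  expect_error(
    integrate_segment(filter_state(c(0, 0)), c(0, 8), pi_motor = 0.25,
                      params = plant_params(dt = 0.01,
                                            segment_duration = 0.25)),
    "unstable")
})

test_that("duration must tile into integration steps", {
  expect_error(
    integrate_segment(filter_state(c(0, 0)), c(0, 8), 1, duration = 0.2505),
    "integer multiple")
})
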