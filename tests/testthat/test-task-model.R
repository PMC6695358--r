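# Delayed oculomotor task: model structure, trial mechanics, the
# premature-saccade rule, and reproducibility.

test_that("the task model has the documented structure", {
  m <- build_model()
  expect_equal(m$n_states, c(5L, 4L, 4L))
  expect_equal(m$n_outcomes, c(5L, 2L, 3L, 5L))
  expect_equal(m$T, 4L)
  expect_equal(m$controllable, 1L)
  expect_equal(m$n_controls, 5L)
  expect_equal(m$stage_kinds, c("cue", "delay", "go", "feedback"))
  # fixation is the only controllable factor; target and stage are static
  # or autonomous (single control slice)
  expect_equal(dim(m$B[[1]])[3], 5L)
  expect_equal(dim(m$B[[2]])[3], 1L)
  expect_equal(dim(m$B[[3]])[3], 1L)
  # target dynamics: stability dominates every column
  expect_true(all(diag(m$B[[2]][, , 1]) == max(m$B[[2]])))
  # stage advances deterministically and absorbs at feedback
  expect_equal(m$B[[3]][2, 1, 1], 1)
  expect_equal(m$B[[3]][4, 4, 1], 1)
  # proprioception: modal outcome is the fixation location in every state
  for (fx in 1:5) for (tg in 1:4) for (st in 1:4) {
    expect_equal(which.max(m$A[[4]][, fx, tg, st]), fx)
  }
  # cue visible only during the cue stage
  expect_equal(which.max(m$A[[1]][, 1, 3, 1]), 3L)
  expect_equal(which.max(m$A[[1]][, 1, 3, 2]), 5L)
  # cross red only in delay
  expect_equal(which.max(m$A[[2]][, 1, 1, 2]), 2L)
  expect_equal(which.max(m$A[[2]][, 1, 1, 3]), 1L)
})

test_that("invalid task configuration fails with a descriptive error", {
  expect_error(build_model(eccentricity_deg = -3), "eccentricity")
  expect_error(build_model(c_pref = 0), "c_pref")
  expect_error(build_model(likelihood_fidelity = 0.1), "fidelity")
  expect_error(build_model(n_delay_steps = 0), "delay")
})

test_that("adding a constant to preferences leaves the policy posterior alone", {
  m1 <- build_model(c_pref = 4)
  m2 <- m1
  m2$C <- lapply(m1$C, function(cm) cm + 7.3)
  prec <- precisions()
  wm1 <- weight_model(m1, prec); wm2 <- weight_model(m2, prec)
  obs <- matrix(NA_integer_, 4, 4); obs[, 1] <- c(2L, 1L, 1L, 1L)
  pol <- enumerate_policies(5, 3)
  inf <- ocupharm:::.infer_policies(wm1, obs, pol)
  G1 <- ocupharm:::.efe_policies(wm1, inf$q, 2:4)
  G2 <- ocupharm:::.efe_policies(wm2, inf$q, 2:4)
  p1 <- policy_posterior(inf$F, G1, prec$gamma)
  p2 <- policy_posterior(inf$F, G2, prec$gamma)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-9)
  expect_equal(p1$prior, p2$prior, tolerance = 1e-9)
})

test_that("a default-precision trial reproduces correct task performance", {
  m <- build_model()
  tr <- run_trial(m, precisions(), "left", seed = 4)
  expect_true(tr$correct)
  expect_false(tr$premature)
  # the saccade is withheld until go: fixation holds through delay and go
  expect_equal(tr$actions[1:2], c(1L, 1L))
  expect_equal(tr$actions[3], 4L)  # "left"
  # exactly one saccade event, in the final segment
  sm <- tr$segment_metrics
  expect_equal(sum(sm$n_saccades[sm$segment < 4]), 0)
  expect_equal(sm$n_saccades[sm$segment == 4], 1)
  # endpoint within 1 degree of the target
  expect_lt(tr$metrics$endpoint_error, 1)
})

test_that("a trial spans four 250 ms segments sampled at 1 ms", {
  tr <- run_trial(build_model(), precisions(), "up", seed = 1)
  expect_equal(nrow(tr$trajectory), 1000L)
  expect_equal(max(tr$trajectory$time_s), 1, tolerance = 1e-9)
  expect_equal(sort(unique(tr$trajectory$segment)), 1:4)
  expect_equal(as.vector(table(tr$trajectory$segment)), rep(250L, 4))
})

test_that("premature fixation changes force incorrect feedback", {
  m <- build_model()
  # process rule, directly: moving during delay emits incorrect immediately
  expect_equal(ocupharm:::.process_outcomes(m, 2, fix_state = 3L,
                                            target_state = 2L,
                                            premature = TRUE)[["feedback"]], 3L)
  # and the final feedback stays incorrect even if the eye lands on target
  expect_equal(ocupharm:::.process_outcomes(m, 4, fix_state = 3L,
                                            target_state = 2L,
                                            premature = TRUE)[["feedback"]], 3L)
  # without a premature move, landing on target is correct
  expect_equal(ocupharm:::.process_outcomes(m, 4, fix_state = 3L,
                                            target_state = 2L,
                                            premature = FALSE)[["feedback"]], 2L)
  # end-to-end: any trial flagged premature must be scored incorrect
  seeds <- ocupharm:::trial_seeds(21, 40)
  batch <- lapply(seeds, function(s) {
    run_trial(m, precisions(beta = 16), "up", seed = s, plant = FALSE)
  })
  prem <- vapply(batch, function(t) t$premature, logical(1))
  corr <- vapply(batch, function(t) t$correct, logical(1))
  expect_gt(sum(prem), 0)           # low gamma does produce premature moves
  expect_true(all(!corr[prem]))
})

test_that("policy-averaged beliefs equal the pi-weighted sum of per-policy beliefs", {
  tr <- run_trial(build_model(), precisions(), "down", seed = 2, plant = FALSE)
  for (t in 1:4) {
    st <- tr$beliefs[[t]]
    ns <- dim(st$q[[2]])[1]; Tt <- dim(st$q[[2]])[2]; P <- dim(st$q[[2]])[3]
    manual <- matrix(st$q[[2]], ns * Tt, P) %*% st$pi
    expect_equal(as.vector(manual), as.vector(st$bma[[2]]), tolerance = 1e-9)
    expect_equal(as.vector(st$bma[[2]]), as.vector(tr$bma_target[, , t]),
                 tolerance = 1e-12)
  }
})

test_that("trials are reproducible under a fixed seed", {
  m <- build_model()
  a <- run_trial(m, precisions(beta = 4), "right", seed = 123)
  b <- run_trial(m, precisions(beta = 4), "right", seed = 123)
  expect_identical(a$actions, b$actions)
  expect_identical(a$outcomes, b$outcomes)
  expect_equal(a$trajectory, b$trajectory, tolerance = 1e-15)
  expect_equal(a$gamma_trace, b$gamma_trace, tolerance = 1e-15)
})

test_that("extra delay steps extend the trial coherently", {
  m <- build_model(n_delay_steps = 2)
  expect_equal(m$T, 5L)
  expect_equal(m$stage_kinds, c("cue", "delay", "delay", "go", "feedback"))
  tr <- run_trial(m, precisions(), "up", seed = 5, plant = FALSE)
  expect_true(tr$correct)
  expect_equal(tr$actions, c(1L, 1L, 1L, 2L))
})
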