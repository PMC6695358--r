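# Discrete active-inference machinery: precision weighting, state
# inference against the enumeration oracle, expected free energy, policy
# posteriors, precision updates and action sampling.

test_that("apply_precision limit cases: identity, flattening, sharpening", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  expect_equal(apply_precision(A, 1), A, tolerance = 1e-12)
  flat <- apply_precision(A, 0)
  expect_equal(flat, matrix(0.5, 2, 2), tolerance = 1e-12)
  # hand oracle: square entries and renormalise -> 0.64/0.68, 0.04/0.68
  sq <- apply_precision(matrix(c(0.8, 0.2), 2, 1), 2)
  expect_equal(drop(sq), c(0.941, 0.059), tolerance = 1e-3)
  # zero-temperature limit: one-hot on the argmax
  sharp <- apply_precision(A, 200)
  expect_equal(drop(sharp[, 1]), c(1, 0), tolerance = 1e-9)
  expect_equal(drop(sharp[, 2]), c(0, 1), tolerance = 1e-9)
  # zeros floored, then identity within tolerance
  Az <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(apply_precision(Az, 1), Az, tolerance = 1e-9)
  expect_error(apply_precision(A, -1), "non-negative")
})

test_that("apply_precision preserves shape and normalisation on 3-d arrays", {
  set.seed(42)
  B <- array(rand_cols(3, 9), dim = c(3, 3, 3))
  for (prec in c(0, 0.5, 1, 2, 10)) {
    W <- apply_precision(B, prec)
    expect_identical(dim(W), dim(B))
    cols <- matrix(W, nrow = 3)
    expect_true(max(abs(colSums(cols) - 1)) < 1e-9)
  }
})

test_that("single-observation inference matches exact Bayes (printed toy)", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  m <- toy_model(A, B = diag(2), D = c(0.5, 0.5), T = 1)
  wm <- weight_model(m, precisions(zeta = 1, omega = 1))
  res <- infer_states(wm, outcomes = 1L)
  oracle <- brute_posterior(wm, obs_matrix(m, 1L))
  expect_equal(res$posterior[[1]], oracle[[1]], tolerance = 1e-6)
  # direct Bayes rule: likelihood column for o = 1, uniform prior
  expect_equal(drop(res$posterior[[1]]), c(0.9, 0.1), tolerance = 1e-6)
})

test_that("noiseless models identify the unique consistent state sequence", {
  A <- diag(3)
  B <- rand_perm(3)
  m <- toy_model(A, B, D = rep(1 / 3, 3), T = 3)
  wm <- weight_model(m, precisions(zeta = 1, omega = 1))
  s1 <- 2L
  path <- c(s1, which(B[, s1] == 1), which(B %*% B[, s1] == 1))
  obs <- obs_matrix(m, path[1], path[2], path[3])
  res <- infer_states(wm, obs)
  for (tau in 1:3) {
    expect_equal(res$posterior[[1]][path[tau], tau], 1, tolerance = 1e-6)
  }
})

test_that("zero likelihood precision makes outcomes uninformative", {
  set.seed(7)
  A <- rand_cols(3, 3)
  B <- rand_cols(3, 3)
  m <- toy_model(A, B, D = c(0.6, 0.3, 0.1), T = 3)
  wm <- weight_model(m, precisions(zeta = 0, omega = 1))
  # posteriors are determined by D and B alone: any two outcome sequences
  # give identical beliefs
  r1 <- infer_states(wm, obs_matrix(m, 2L, 1L, 3L))
  r2 <- infer_states(wm, obs_matrix(m, 1L, 3L, 2L))
  expect_equal(r1$posterior[[1]], r2$posterior[[1]], tolerance = 1e-9)
  # and the uninformed posterior is the prior chain D, BD, BBD
  Bw <- weight_model(m, precisions(zeta = 0, omega = 1))$B[[1]][, , 1]
  expect_equal(r1$posterior[[1]][, 1], wm$D[[1]], tolerance = 1e-6)
  expect_equal(r1$posterior[[1]][, 2], drop(Bw %*% wm$D[[1]]), tolerance = 1e-6)
  expect_equal(r1$posterior[[1]][, 3], drop(Bw %*% Bw %*% wm$D[[1]]),
               tolerance = 1e-6)
})

test_that("inference agrees with brute-force enumeration on toy models", {
  for (seed in 1:6) {
    set.seed(seed)
    # (a) T = 1, two modalities, 3 states
    m <- mdp_model(A = list(rand_cols(3, 3), rand_cols(2, 3)),
                   B = list(diag(3)), C = list(matrix(0, 3, 1), matrix(0, 2, 1)),
                   D = list(c(0.5, 0.3, 0.2)), T = 1)
    wm <- weight_model(m, precisions(zeta = 1, omega = 1))
    obs <- obs_matrix(m, c(sample.int(3, 1), sample.int(2, 1)))
    res <- infer_states(wm, obs)
    oracle <- brute_posterior(wm, obs)
    expect_lt(max(abs(res$posterior[[1]] - oracle[[1]])), 1e-3)

    # (b) T = 3, arbitrary noisy transitions (chains are smoothed exactly)
    m2 <- toy_model(rand_cols(3, 3), rand_cols(3, 3), D = c(0.2, 0.5, 0.3),
                    T = 3)
    wm2 <- weight_model(m2, precisions(zeta = 1, omega = 1))
    obs2 <- obs_matrix(m2, sample.int(3, 1), sample.int(3, 1), sample.int(3, 1))
    res2 <- infer_states(wm2, obs2)
    oracle2 <- brute_posterior(wm2, obs2)
    expect_lt(max(abs(res2$posterior[[1]] - oracle2[[1]])), 1e-3)

    # (c) T = 3, deterministic permutation transitions, noisy likelihood
    m3 <- toy_model(rand_cols(3, 3), rand_perm(3), D = rep(1 / 3, 3), T = 3)
    wm3 <- weight_model(m3, precisions(zeta = 1, omega = 1))
    obs3 <- obs_matrix(m3, sample.int(3, 1), sample.int(3, 1), sample.int(3, 1))
    res3 <- infer_states(wm3, obs3)
    oracle3 <- brute_posterior(wm3, obs3)
    expect_lt(max(abs(res3$posterior[[1]] - oracle3[[1]])), 1e-3)

    # (d) partial observation: only the first step observed
    m4 <- toy_model(rand_cols(2, 2), rand_cols(2, 2), D = c(0.7, 0.3), T = 3)
    wm4 <- weight_model(m4, precisions(zeta = 1, omega = 1))
    obs4 <- obs_matrix(m4, sample.int(2, 1))
    res4 <- infer_states(wm4, obs4)
    oracle4 <- brute_posterior(wm4, obs4)
    expect_lt(max(abs(res4$posterior[[1]] - oracle4[[1]])), 1e-3)
  }
})

test_that("variational free energy is non-increasing across iterations", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- toy_model(rand_cols(3, 3), rand_cols(3, 3),
                   D = .norm <- c(0.2, 0.5, 0.3), T = 3)
    wm <- weight_model(m, precisions(zeta = 1, omega = 1))
    obs <- obs_matrix(m, sample.int(3, 1), sample.int(3, 1), sample.int(3, 1))
    res <- infer_states(wm, obs)
    expect_true(all(diff(res$F_trace) <= 1e-6))
  }
})

test_that("posteriors stay normalised at every time step and policy", {
  m <- build_model()
  wm <- weight_model(m, precisions())
  obs <- matrix(NA_integer_, 4, 4); obs[, 1] <- c(2L, 1L, 1L, 1L)
  pol <- enumerate_policies(5, 3)
  res <- ocupharm:::.infer_policies(wm, obs, pol)
  for (f in seq_along(res$q)) {
    sums <- apply(res$q[[f]], c(2, 3), sum)
    expect_true(max(abs(sums - 1)) < 1e-9)
  }
})

test_that("expected free energy separates into risk and ambiguity", {
  # deterministic A, predictions equal to the preference target -> G = 0
  m <- toy_model(diag(2), diag(2), D = c(0.5, 0.5), T = 2,
                 C = list(matrix(0, 2, 2)))
  wm <- weight_model(m, precisions(zeta = 1, omega = 1))
  beliefs <- list(matrix(0.5, 2, 2))
  G0 <- expected_free_energy(wm, policy = 1L, beliefs, future_tau = 2L)
  expect_equal(as.numeric(G0), 0, tolerance = 1e-6)

  # deterministic A, one-hot prediction against a flat target -> KL = ln 2
  beliefs1 <- list(matrix(c(0.5, 0.5, 1, 0), 2, 2))
  G1 <- expected_free_energy(wm, policy = 1L, beliefs1, future_tau = 2L)
  expect_equal(as.numeric(G1), log(2), tolerance = 1e-6)

  # uniform likelihood column: ambiguity contributes ln 2 per step
  mu <- toy_model(matrix(0.5, 2, 2), diag(2), D = c(0.5, 0.5), T = 2,
                  C = list(matrix(0, 2, 2)))
  wmu <- weight_model(mu, precisions(zeta = 1, omega = 1))
  Gu <- expected_free_energy(wmu, policy = 1L, beliefs, future_tau = 2L)
  expect_equal(as.numeric(Gu), log(2), tolerance = 1e-6)
})

test_that("policy posterior softmax: hand values, limits, shift invariance", {
  pp <- policy_posterior(F = c(0, 0), G = c(0, 1), gamma = 1)
  expect_equal(pp$posterior, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(pp$prior, pp$posterior, tolerance = 1e-12)

  # gamma -> 0: all plans equally probable
  pp0 <- policy_posterior(F = c(0.3, 0.3, 0.3), G = c(5, 1, 9), gamma = 1e-12)
  expect_equal(pp0$prior, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(pp0$posterior, rep(1 / 3, 3), tolerance = 1e-9)

  # zero-temperature limit: one-hot on the argmin of G
  pph <- policy_posterior(F = c(0, 0, 0), G = c(2, 0.5, 3), gamma = 500)
  expect_equal(pph$posterior, c(0, 1, 0), tolerance = 1e-6)

  # adding constants to G or F leaves both distributions unchanged
  set.seed(3)
  G <- runif(5); F <- runif(5)
  a <- policy_posterior(F, G, gamma = 1.7)
  b <- policy_posterior(F + 3.2, G - 11, gamma = 1.7)
  expect_equal(a$prior, b$prior, tolerance = 1e-9)
  expect_equal(a$posterior, b$posterior, tolerance = 1e-9)

  expect_error(policy_posterior(F, G, gamma = 0), "positive")
  expect_error(policy_posterior(F, G, gamma = -1), "positive")
})

test_that("precision updates mimic dopamine transients", {
  G <- c(0.5, 2, 3)
  pi_prior <- softmax(-G)
  # no belief update, no transient
  up0 <- update_precision(1, G, pi_prior, pi_prior)
  expect_equal(up0$beta, 1, tolerance = 1e-12)
  expect_false(up0$clipped)
  # posterior mass moves to the lowest-G policy: beta falls, gamma bursts
  pi_conf <- c(0.95, 0.04, 0.01)
  up1 <- update_precision(1, G, pi_conf, pi_prior)
  expect_lt(up1$beta, 1)
  expect_gt(up1$gamma, 1)
  # posterior mass moves to a high-G policy: gamma dips
  pi_bad <- c(0.05, 0.15, 0.8)
  up2 <- update_precision(1, G, pi_bad, pi_prior)
  expect_gt(up2$beta, 1)
  expect_lt(up2$gamma, 1)
  # positivity clip engages
  up3 <- update_precision(0.02, c(0, 100), c(1, 0), c(0, 1))
  expect_true(up3$clipped)
  expect_equal(up3$beta, 1 / 64)
})

test_that("action sampling marginalises policies and is seed-reproducible", {
  pol <- matrix(c(1L, 1L, 2L), 3, 1)
  # one-hot posterior: that policy's action, surely
  sa <- sample_action(c(0, 0, 1), pol, seed = 1)
  expect_equal(sa$action, 2L)
  expect_equal(sa$marginal, c(0, 1))
  # counting oracle: uniform over {u1, u1, u2} -> marginal (2/3, 1/3)
  sb <- sample_action(rep(1 / 3, 3), pol, seed = 1)
  expect_equal(sb$marginal, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # determinism under a fixed seed
  draws1 <- vapply(1:20, function(i) sample_action(rep(1 / 3, 3), pol,
                                                   seed = 99 + i)$action,
                   integer(1))
  draws2 <- vapply(1:20, function(i) sample_action(rep(1 / 3, 3), pol,
                                                   seed = 99 + i)$action,
                   integer(1))
  expect_identical(draws1, draws2)
})

test_that("policy enumeration covers the control space and honours the cap", {
  pol <- enumerate_policies(5, 3)
  expect_equal(dim(pol), c(125L, 3L))
  expect_equal(nrow(unique(pol)), 125L)
  expect_true(all(pol >= 1 & pol <= 5))
  expect_equal(dim(enumerate_policies(5, 4, cap = 2)), c(25L, 2L))
  expect_equal(ncol(enumerate_policies(3, 0)), 0L)
})
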