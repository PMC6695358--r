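# Independent oracles and toy-model builders used across the suite.

# Exact posterior marginals by brute-force enumeration over joint hidden
# state sequences. Deliberately naive: enumerates every sequence and
# applies Bayes' rule directly. Works on the same precision-weighted
# (floored) arrays the engine consumes.
brute_posterior <- function(wm, obs, actions = integer(0)) {
  nf <- wm$n_factors; ns <- wm$n_states; Tt <- wm$T
  joint <- as.matrix(expand.grid(lapply(ns, seq_len)))
  nj <- nrow(joint)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(nj)), Tt)))
  if (length(actions) < Tt - 1) actions <- c(actions, rep(1L, Tt - 1 - length(actions)))
  strides <- cumprod(c(1, ns[-nf]))
  lw <- numeric(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    l <- 0
    for (f in seq_len(nf)) {
      s_path <- joint[seqs[i, ], f]
      l <- l + log(wm$D[[f]][s_path[1]])
      if (Tt > 1) for (tau in 2:Tt) {
        u <- if (f == wm$controllable && dim(wm$B[[f]])[3] > 1) actions[tau - 1] else 1L
        l <- l + log(wm$B[[f]][s_path[tau], s_path[tau - 1], u])
      }
    }
    for (tau in seq_len(Tt)) {
      idx <- 1 + sum((joint[seqs[i, tau], ] - 1) * strides)
      for (m in seq_len(wm$n_modalities)) {
        o <- obs[m, tau]
        if (!is.na(o)) l <- l + log(wm$A_flat[[m]][o, idx])
      }
    }
    lw[i] <- l
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  lapply(seq_len(nf), function(f) {
    mar <- matrix(0, ns[f], Tt)
    for (tau in seq_len(Tt)) {
      s <- joint[seqs[, tau], f]
      for (k in seq_len(ns[f])) mar[k, tau] <- sum(w[s == k])
    }
    mar
  })
}

# Single-factor toy model builder (one controllable=no control slice).
toy_model <- function(A, B, D, T, C = NULL) {
  A <- if (is.list(A)) A else list(A)
  no <- vapply(A, nrow, integer(1))
  if (is.null(C)) C <- lapply(no, function(n) matrix(0, n, T))
  mdp_model(A = A, B = list(B), C = C, D = list(D), T = T, controllable = 1L)
}

# Random categorical matrix with strictly positive entries (columns sum 1).
rand_cols <- function(nr, nc) {
  m <- matrix(stats::runif(nr * nc, 0.05, 1), nr, nc)
  sweep(m, 2, colSums(m), "/")
}

# Random permutation (deterministic) transition matrix.
rand_perm <- function(n) {
  p <- sample.int(n)
  m <- matrix(0, n, n)
  m[cbind(p, seq_len(n))] <- 1
  m
}

obs_matrix <- function(model, ...) {
  o <- matrix(NA_integer_, model$n_modalities, model$T)
  vals <- list(...)
  for (tau in seq_along(vals)) if (!is.null(vals[[tau]])) o[, tau] <- vals[[tau]]
  o
}

expect_normalised <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
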