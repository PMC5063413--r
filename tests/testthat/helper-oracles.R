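# Independent oracles used to cross-check package computations.

# Expected absorption time of the unbiased Go/Stay walk on an n-state chain,
# from the fundamental matrix of the transient part of the transition matrix
# (one step per occupied state, start and goal included).
absorption_steps_oracle <- function(n_states) {
  m <- n_states - 1L
  P <- matrix(0, m, m)
  for (i in seq_len(m)) {
    P[i, i] <- 0.5
    if (i < m) P[i, i + 1L] <- 0.5
  }
  expected <- solve(diag(m) - P, rep(1, m))
  expected[1L] + 1  # + the goal-occupancy step
}

# Equilibria of the reduced model by 1-D scanning: the Go value equation is
# linear (q12* = alpha r / (alpha + psi)); the Stay nullcline residual is
# scanned for sign changes and polished with uniroot.
reduced_equilibria_oracle <- function(params, n_grid = 2000L) {
  q12 <- params$alpha * params$r / (params$alpha + params$psi)
  g <- function(q11)
    exp(params$beta * (q11 - q12)) * params$alpha *
      (params$gamma * q12 - q11) - params$psi * q11
  xs <- seq(0, q12, length.out = n_grid)
  ys <- vapply(xs, g, numeric(1))
  roots <- c()
  for (i in seq_len(n_grid - 1L)) {
    if (ys[i] == 0) roots <- c(roots, xs[i])
    else if (ys[i] * ys[i + 1L] < 0)
      roots <- c(roots, stats::uniroot(g, c(xs[i], xs[i + 1L]),
                                       tol = 1e-12)$root)
  }
  if (ys[n_grid] == 0) roots <- c(roots, xs[n_grid])
  cbind(q11 = unique(roots), q12 = q12)
}

# Batch of independently seeded sessions.
run_sessions <- function(env, params, n_sessions, n_trials, base_seed = 1L,
                         ...) {
  lapply(base_seed + seq_len(n_sessions) - 1L, function(sd)
    run_session(env, params, n_trials, seed = sd, ...))
}
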