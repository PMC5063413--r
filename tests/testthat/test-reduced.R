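test_that("the reduced right-hand side matches hand evaluation", {
  p <- reduced_params()  # alpha 0.5, beta 5, gamma 1, r 1, psi 0
  # decay-free fixed point at (r, r)
  expect_equal(unname(reduced_rhs(c(1, 1), p)), c(0, 0))
  # q11 = q12 makes the Stay-repetition factor y equal 1
  f <- reduced_rhs(c(0.3, 0.3), p)
  expect_equal(unname(f[1]), 0.5 * (0.3 - 0.3))
  p2 <- reduced_params(psi = 0.06)
  f2 <- reduced_rhs(c(0.2, 1.0), p2)
  expect_equal(unname(f2[2]), 0.5 * (1 - 1.0) - 0.06 * 1.0)
  expect_equal(unname(f2[1]),
               exp(5 * (0.2 - 1)) * 0.5 * (1 - 0.2) - 0.06 * 0.2)
})

test_that("equilibria and stability track the decay degree", {
  # no decay: single stable equilibrium at (r, r)
  eq0 <- find_equilibria(reduced_params(psi = 0))
  expect_equal(nrow(eq0), 1)
  expect_equal(c(eq0$q11, eq0$q12), c(1, 1), tolerance = 1e-8)
  expect_equal(eq0$stability, "stable")
  # bistable window: two stable equilibria separated by a saddle
  eqb <- find_equilibria(reduced_params(psi = 0.05))
  expect_equal(nrow(eqb), 3)
  expect_equal(sum(eqb$stability == "stable"), 2)
  expect_equal(sum(eqb$stability == "saddle"), 1)
  expect_equal(eqb$q11[1] < eqb$q11[2] && eqb$q11[2] < eqb$q11[3], TRUE)
  # beyond the upper fold: unique stable equilibrium with a large contrast
  eq8 <- find_equilibria(reduced_params(psi = 0.08))
  expect_equal(nrow(eq8), 1)
  expect_equal(eq8$stability, "stable")
  expect_gt(eq8$q12 - eq8$q11, 0.5)
  # residual vanishes at every reported equilibrium
  for (eq in list(eq0, eqb, eq8))
    for (i in seq_len(nrow(eq)))
      expect_lt(max(abs(reduced_rhs(c(eq$q11[i], eq$q12[i]),
                                    reduced_params(psi = eq$psi[i])))),
                1e-9)
})

test_that("multi-start equilibria agree with the 1-D nullcline-scan oracle", {
  for (psi in c(0, 0.02, 0.05, 0.0555, 0.07, 0.1)) {
    p <- reduced_params(psi = psi)
    got <- find_equilibria(p)
    want <- reduced_equilibria_oracle(p)
    expect_equal(nrow(got), nrow(want), info = paste("psi =", psi))
    expect_equal(got$q11, unname(sort(want[, "q11"])), tolerance = 1e-6)
    expect_equal(got$q12, unname(rep(want[1, "q12"], nrow(got))),
                 tolerance = 1e-6)
  }
})

test_that("choice probabilities at equilibrium follow the softmax of the value contrast", {
  eq <- find_equilibria(reduced_params(psi = 0.08))
  expect_equal(eq$p11, plogis(5 * (eq$q11 - eq$q12)))
  # symmetric values give indifference
  eq0 <- find_equilibria(reduced_params(psi = 0))
  expect_equal(eq0$p11, 0.5, tolerance = 1e-6)
})

test_that("the bifurcation diagram has the 1 -> 3 -> 1 branch structure", {
  bd <- bifurcation_sweep(reduced_params(), seq(0, 0.12, by = 0.002),
                          refine = FALSE)
  counts <- table(factor(bd$psi))
  expect_equal(sort(unique(as.integer(counts))), c(1L, 3L))
  psi_by_count <- tapply(bd$psi, bd$psi, unique)
  n_at <- vapply(split(bd, bd$psi), nrow, integer(1))
  psi_vals <- as.numeric(names(n_at))
  three <- psi_vals[n_at == 3]
  expect_true(all(psi_vals[psi_vals < min(three)] >= 0))
  # the 3-branch window is an interval: everything between its ends has 3
  expect_true(all(n_at[psi_vals > min(three) & psi_vals < max(three)] == 3))
  # weak softmax: no bistability anywhere on the same grid
  bd_soft <- bifurcation_sweep(reduced_params(beta = 1),
                               seq(0, 0.12, by = 0.004), refine = FALSE)
  expect_true(all(vapply(split(bd_soft, bd_soft$psi), nrow,
                         integer(1)) == 1L))
})

test_that("bisection localizes the upper saddle-node near 0.0559", {
  psi_star <- find_saddle_node_upper(reduced_params(), tol = 1e-5)
  expect_lt(abs(psi_star - 0.0559), 0.001)
  p_above <- reduced_params(psi = psi_star + 5e-4)
  p_below <- reduced_params(psi = psi_star - 5e-4)
  expect_equal(nrow(find_equilibria(p_above)), 1)
  expect_equal(nrow(find_equilibria(p_below)), 3)
  expect_error(find_saddle_node_upper(reduced_params(),
                                      bracket = c(0.001, 0.002)),
               "bracket")
})

test_that("full-model Stay value fluctuates between two levels inside the bistable regime", {
  # per-step decay 0.0045 at ~9 steps/trial corresponds to a per-trial decay
  # degree ~0.04, inside the bistable window of the reduced model
  env <- linear_track()
  p <- agent_params(phi = 0.0045)
  v <- value_table(env)
  set.seed(17)
  stay6 <- numeric(3000)
  for (tr in seq_along(stay6)) {
    res <- run_trial(env, p, v, trial_index = tr)
    v <- res$values
    stay6[tr] <- v[["Stay@S6"]]
  }
  stay6 <- stay6[-(1:200)]  # discard initial learning
  high <- stay6 > 0.45
  # both levels are visited, each for long stretches of trials
  expect_gt(mean(high), 0.02)
  expect_lt(mean(high), 0.98)
  runs <- rle(high)
  expect_gt(max(runs$lengths[runs$values]), 30)
  expect_gt(max(runs$lengths[!runs$values]), 30)
})

test_that("nullcline field is consistent with the right-hand side", {
  p <- reduced_params(psi = 0.05)
  nc <- reduced_nullclines(p, n = 21)
  i <- sample(nrow(nc), 25)
  for (k in i) {
    f <- reduced_rhs(c(nc$q11[k], nc$q12[k]), p)
    expect_equal(unname(f), c(nc$dq11[k], nc$dq12[k]))
  }
  expect_true(all(nc$in_region == (nc$q11 <= nc$q12)))
})
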