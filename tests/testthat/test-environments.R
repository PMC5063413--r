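test_that("linear track exposes Stay/Go (and optional Back) with the odd/even index convention", {
  env <- linear_track()
  for (i in 1:6) {
    cd <- candidates(env, i)
    expect_equal(unname(cd), c(2L * i - 1L, 2L * i))
    expect_equal(unname(env$act_type[cd]), c("stay", "go"))
  }
  expect_length(candidates(env, 7), 0)  # goal: no action defined
  envb <- linear_track(allow_back = TRUE)
  expect_equal(unname(envb$act_type[candidates(envb, 3)]),
               c("stay", "go", "back"))
  expect_equal(unname(candidates(envb, 1)), c(1L, 2L))  # no Back at start
  expect_error(candidates(env, 8), "invalid state")
})

test_that("track transitions are deterministic and total on candidates", {
  env <- linear_track(allow_back = TRUE)
  expect_equal(transition(env, 3, 5), 3)   # Stay
  expect_equal(transition(env, 3, 6), 4)   # Go
  back3 <- candidates(env, 3)[["Back@S3"]]
  expect_equal(transition(env, 3, back3), 2)
  expect_error(transition(env, 1, back3), "not available")
  for (s in 1:6)
    for (a in candidates(env, s))
      expect_true(transition(env, s, a) %in% c(s - 1L, s, s + 1L))
})

test_that("track rewards: goal reward each arrival, mid-track reward every occupancy step", {
  env <- linear_track(mid_reward = 0.1)
  expect_equal(state_reward(env, 7), 1)
  expect_equal(state_reward(env, 4), 0.1)
  expect_equal(state_reward(env, 4, first_visit = FALSE), 0.1)
  expect_equal(state_reward(env, 2), 0)
  expect_error(linear_track(n_states = 4, mid_reward = 0.1), "n_states >= 5")
  # in a simulated trial every consecutive S4 occupancy step pays x
  p <- agent_params(alpha = 0, beta = 0, phi = 0)
  set.seed(8)
  tr <- run_trial(env, p)
  s4 <- tr$records$state == 4
  expect_true(all(tr$records$reward[s4] == 0.1))
  expect_true(all(tr$records$reward[tr$records$state %in% c(1:3, 5:6)] == 0))
})

test_that("T-maze graph: three candidates at the junction, none at the trial end", {
  for (hc in c(TRUE, FALSE)) {
    env <- tmaze(high_cost = hc)
    expect_length(candidates(env, 4), 3)
    expect_length(candidates(env, 9), 0)
    for (s in c(1:3, 5:8)) expect_length(candidates(env, s), 2)
    expect_equal(transition(env, 4, env$arm_actions[1]), 5)
    expect_equal(transition(env, 4, env$arm_actions[2]), 6)
    expect_equal(transition(env, 7, candidates(env, 7)[["Go@S7"]]), 9)
    expect_equal(transition(env, 8, candidates(env, 8)[["Go@S8"]]), 9)
  }
})

test_that("T-maze rewards are first-visit only, placed by cost condition", {
  hc <- tmaze(high_cost = TRUE)
  expect_equal(state_reward(hc, 7), 1)    # large reward behind State 5
  expect_equal(state_reward(hc, 6), 0.5)
  expect_equal(state_reward(hc, 6, first_visit = FALSE), 0)
  expect_equal(state_reward(hc, 5), 0)
  nc <- tmaze(high_cost = FALSE)
  expect_equal(state_reward(nc, 5), 1)    # both arms one Go from junction
  expect_equal(state_reward(nc, 6), 0.5)
  expect_equal(state_reward(nc, 7), 0)
  # simulated: at most one delivery per reward state per trial
  set.seed(4)
  s <- run_session(hc, agent_params(phi = 0.01), 50, seed = 4,
                   record_steps = TRUE)
  per_trial <- tapply(s$steps$reward > 0, s$steps$trial, sum)
  expect_true(all(per_trial <= 2))  # can pass both reward states at most once
  expect_true(all(tapply(s$steps$reward, s$steps$trial, sum) %in%
                    c(0, 0.5, 1, 1.5)))
})

test_that("edge list export matches the environment tables", {
  env <- tmaze()
  el <- env_edge_list(env)
  expect_equal(nrow(el), env$n_actions)
  expect_equal(el$to[el$label == "GoArm1@S4"], 5)
  expect_equal(el$from, env$act_state)
})

test_that("every track trial reaches the goal in finite time for finite beta", {
  set.seed(99)
  for (beta in c(0, 2, 10)) {
    s <- run_session(linear_track(n_states = 4), agent_params(beta = beta),
                     20, seed = 99)
    expect_true(s$completed)
    expect_true(all(s$trials$steps >= 4))
  }
})

test_that("T-maze latency and arm choice are logged per trial", {
  s <- run_session(tmaze(), agent_params(phi = 0.01), 100, seed = 6)
  expect_true(all(s$trials$latency >= 4))  # start + 2 stem + junction
  expect_true(all(s$trials$arm %in% 1:2))
  m <- tmaze_metrics(list(s), block = 10)
  expect_equal(nrow(m), 10)
  expect_true(all(m$arm1_ratio >= 0 & m$arm1_ratio <= 1))
  # all-arm-1 sessions give ratio exactly 1
  fake <- s
  fake$trials$arm <- 1L
  expect_true(all(tmaze_metrics(list(fake))$arm1_ratio == 1))
})
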