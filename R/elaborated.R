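#' Kinematic T-maze with loose state-location coupling
#'
#' An elaborated T-maze in which the subject moves along a continuous path
#' and each internal (learned) state corresponds to a range of physical
#' locations. The stem runs from position 0 to `stem_length` with unit-length
#' half-open bins (state `i` covers `[i-1, i)`); the T-junction is the single
#' point at position `stem_length`. Each arm runs from the junction to its
#' reward location at distance `arm1_length` / `arm2_length`; an arm longer
#' than 1 has one pre-reward internal state covering the open interval before
#' the reward location.
#'
#' Actions: at the start, `Go` (displacement 1) or `Stay`; at stem and
#' pre-reward interior states, `Go` (displacement 1) or `Slow` (displacement
#' half of the previous step's displacement); at the junction, `GoArm1`,
#' `GoArm2` (enter the arm, displacement 1) or `Stay`. Movement is clipped at
#' the junction and at reward locations: the subject moves there whenever the
#' landmark is within the computed displacement. Because states are ranges,
#' an internal-state transition can occur under `Slow`, and the state can
#' repeat while the position still advances. At the reward location the
#' subject takes a consummatory action (no learned value, one time step) and
#' proceeds to the end state, from which it is automatically returned to the
#' start.
#'
#' With the defaults the high-cost condition gives the large-reward arm an
#' extra pre-reward state (`arm1_length = 2`) while the small-reward arm is
#' one unit long; without high cost both arms are one unit long.
#'
#' @param high_cost Large-reward arm carries the extra pre-reward state?
#' @param reward_large Reward at the end of Arm 1 (default 1).
#' @param reward_small Reward at the end of Arm 2 (default 0.5).
#' @param stem_length Integer stem length in position units (default 3).
#' @param arm1_length,arm2_length Arm lengths in position units (`>= 1`).
#' @return An environment object of class `c("elab_tmaze", "rlenv")`.
#' @export
elaborated_tmaze <- function(high_cost = TRUE, reward_large = 1,
                             reward_small = 0.5, stem_length = 3L,
                             arm1_length = if (high_cost) 2 else 1,
                             arm2_length = 1) {
  stem_length <- as.integer(stem_length)
  stopifnot(stem_length >= 2L, arm1_length >= 1, arm2_length >= 1,
            reward_large > 0, reward_small > 0)
  roles <- c(rep("stem", stem_length), "junction")
  roles[1] <- "start"
  arm_pre <- c(NA_integer_, NA_integer_)
  arm_rew <- integer(2)
  for (a in 1:2) {
    len <- if (a == 1L) arm1_length else arm2_length
    if (len > 1) {
      roles <- c(roles, "arm_pre")
      arm_pre[a] <- length(roles)
    }
    roles <- c(roles, "reward")
    arm_rew[a] <- length(roles)
  }
  roles <- c(roles, "end")
  n_states <- length(roles)
  junction <- stem_length + 1L
  end <- n_states
  labels <- character(0); nxt <- integer(0)
  act_state <- integer(0); act_type <- character(0)
  cand <- vector("list", n_states)
  add <- function(label, state, type) {
    id <- length(labels) + 1L
    labels[id] <<- label
    nxt[id] <<- NA_integer_  # kinematic: successor depends on position
    act_state[id] <<- state; act_type[id] <<- type
    cand[[state]] <<- c(cand[[state]], id)
    id
  }
  for (s in seq_len(n_states)) {
    switch(roles[s],
      start = {
        add(sprintf("Stay@S%d", s), s, "stay")
        add(sprintf("Go@S%d", s), s, "go")
      },
      stem = {
        add(sprintf("Slow@S%d", s), s, "slow")
        add(sprintf("Go@S%d", s), s, "go")
      },
      junction = {
        add(sprintf("Stay@S%d", s), s, "stay")
        add(sprintf("GoArm1@S%d", s), s, "go")
        add(sprintf("GoArm2@S%d", s), s, "go")
      },
      arm_pre = {
        add(sprintf("Slow@S%d", s), s, "slow")
        add(sprintf("Go@S%d", s), s, "go")
      },
      reward = , end = {
        cand[[s]] <- integer(0)
      })
  }
  arm_actions <- cand[[junction]][2:3]
  fv <- numeric(n_states)
  fv[arm_rew[1]] <- reward_large
  fv[arm_rew[2]] <- reward_small
  structure(
    list(kind = "elab_tmaze", n_states = n_states, start = 1L,
         terminal = end, n_actions = length(labels), cand = cand,
         nxt = nxt, act_state = act_state, act_type = act_type,
         act_label = labels, occ_reward = numeric(n_states),
         fv_reward = fv, junction = junction, arm_actions = arm_actions,
         roles = roles, stem_length = stem_length,
         arm_length = c(arm1_length, arm2_length), arm_pre = arm_pre,
         arm_rew = arm_rew, high_cost = high_cost,
         reward_large = reward_large, reward_small = reward_small),
    class = c("elab_tmaze", "rlenv")
  )
}

# Internal state corresponding to a physical location.
elab_bin <- function(env, phase, pos) {
  if (phase == 0L) {  # stem
    if (pos >= env$stem_length) env$junction else as.integer(floor(pos)) + 1L
  } else {
    len <- env$arm_length[phase]
    if (pos >= len) env$arm_rew[phase] else env$arm_pre[phase]
  }
}

#' Kinematic displacement and state transition
#'
#' Pure kinematics of one action in the elaborated T-maze: computes the
#' displacement (`Go`: 1; `Slow`: half of the previous displacement; `Stay`:
#' 0; `GoArm*`: 1 along the chosen arm), clips it at the junction or the
#' arm's reward location, and bins the new position into an internal state.
#' `phase` is 0 on the stem, 1 or 2 on an arm; positions are measured from
#' the start of the current segment.
#'
#' @param env An [elaborated_tmaze()] environment.
#' @param phase Current segment (0 stem, 1 Arm 1, 2 Arm 2).
#' @param pos Position along the current segment.
#' @param last_disp Displacement during the previous time interval.
#' @param action One of `"go"`, `"slow"`, `"stay"`, `"go_arm1"`,
#'   `"go_arm2"`.
#' @return A list `phase`, `pos`, `disp` (actual, post-clipping
#'   displacement), `state` (internal state id after the move).
#' @examples
#' env <- elaborated_tmaze()
#' advance_position(env, 0, 1, 1, "slow")   # half speed after a Go
#' @export
advance_position <- function(env, phase, pos, last_disp, action) {
  stopifnot(inherits(env, "elab_tmaze"), last_disp >= 0)
  phase <- as.integer(phase)
  state <- elab_bin(env, phase, pos)
  role <- env$roles[state]
  if (action %in% c("go_arm1", "go_arm2")) {
    if (role != "junction") stop("arm entry is only possible at the junction")
    phase <- if (action == "go_arm1") 1L else 2L
    pos <- 0
    intended <- 1
  } else if (action == "stay") {
    if (!role %in% c("start", "junction"))
      stop("'Stay' exists only at the start and the junction")
    intended <- 0
  } else if (action == "go") {
    intended <- 1
  } else if (action == "slow") {
    if (role %in% c("start", "junction", "reward", "end"))
      stop("'Slow' is not available at a physically constrained state")
    intended <- last_disp / 2
  } else stop("unknown action: ", action)
  limit <- if (phase == 0L) env$stem_length else env$arm_length[phase]
  new_pos <- pos + intended
  if (new_pos >= limit) new_pos <- limit
  disp <- new_pos - pos
  list(phase = phase, pos = new_pos, disp = disp,
       state = elab_bin(env, phase, new_pos))
}

# One elaborated trial; Q-learning RPE, update-then-decay per counted step.
# Records the arrival displacement (displacement during the previous
# interval) per step; NA at the first step of the trial.
elab_trial_core <- function(env, params, values, factor, max_steps) {
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  keep <- 1 - params$phi
  occ <- env$occ_reward; fv <- env$fv_reward
  cand <- env$cand
  phase <- 0L; pos <- 0; last <- 0
  state <- 1L
  prev <- 0L
  seen <- logical(env$n_states)
  cap <- 64L
  st_v <- integer(cap); ac_v <- integer(cap)
  de_v <- numeric(cap); rw_v <- numeric(cap); dp_v <- numeric(cap)
  t <- 0L
  runaway <- FALSE
  repeat {
    if (t >= max_steps) { runaway <- TRUE; break }
    t <- t + 1L
    if (t > cap) {
      cap <- cap * 2L
      length(st_v) <- cap; length(ac_v) <- cap
      length(de_v) <- cap; length(rw_v) <- cap; length(dp_v) <- cap
    }
    r <- occ[[state]]
    if (fv[[state]] != 0 && !seen[[state]]) {
      r <- r + fv[[state]]
      seen[[state]] <- TRUE
    }
    cd <- cand[[state]]
    nc <- length(cd)
    future <- if (nc == 0L) 0 else max(values[cd])
    delta <- r + gamma * future - (if (prev > 0L) values[[prev]] else 0)
    st_v[t] <- state; de_v[t] <- delta; rw_v[t] <- r
    dp_v[t] <- if (t == 1L) NA_real_ else last
    if (prev > 0L)
      values[[prev]] <- values[[prev]] + alpha * factor * delta
    values <- values * keep
    role <- env$roles[state]
    if (role == "end") { ac_v[t] <- NA_integer_; break }
    if (role == "reward") {
      # consummatory action: one step, no learned value, go to the end state
      ac_v[t] <- NA_integer_
      prev <- 0L
      state <- env$terminal
      last <- 0
      next
    }
    a_cur <- cd[[softmax_pick(values[cd], beta)]]
    ac_v[t] <- a_cur
    lbl <- env$act_label[[a_cur]]
    act <- if (startsWith(lbl, "Stay")) "stay"
      else if (startsWith(lbl, "Slow")) "slow"
      else if (startsWith(lbl, "GoArm1")) "go_arm1"
      else if (startsWith(lbl, "GoArm2")) "go_arm2"
      else "go"
    mv <- advance_position(env, phase, pos, last, act)
    phase <- mv$phase; pos <- mv$pos; last <- mv$disp
    state <- mv$state
    prev <- a_cur
  }
  idx <- seq_len(t)
  list(steps = t, values = values, runaway = runaway,
       state = st_v[idx], action = ac_v[idx], delta = de_v[idx],
       reward = rw_v[idx], disp = dp_v[idx])
}

#' Run a session of the elaborated kinematic T-maze
#'
#' As [run_session()], but on an [elaborated_tmaze()] environment with
#' continuous positions. The per-step log additionally records `disp`, the
#' displacement during the interval leading into each step's state (`NA` at
#' the first step of a trial). Learning uses the Q-learning RPE with the
#' same update-then-decay ordering as the discrete agent.
#'
#' @inheritParams run_session
#' @param env An [elaborated_tmaze()] environment.
#' @return A `session_result`; `trials` has `latency` (steps through the
#'   first junction occupancy) and `arm` columns, and `steps` the per-step
#'   log when `record_steps = TRUE`.
#' @export
run_session_elab <- function(env, params, n_trials, seed,
                             manipulation = NULL, step_cap = Inf,
                             record_steps = TRUE) {
  stopifnot(inherits(env, "elab_tmaze"), inherits(params, "agent_params"),
            params$algorithm == "q_learning", n_trials >= 1)
  n_trials <- as.integer(n_trials)
  set.seed(as.integer(seed))
  values <- numeric(env$n_actions)
  steps_v <- integer(n_trials); reward_v <- numeric(n_trials)
  dsum_v <- numeric(n_trials)
  lat_v <- rep(NA_integer_, n_trials); arm_v <- rep(NA_integer_, n_trials)
  logs <- if (record_steps) vector("list", n_trials) else NULL
  total <- 0L; done <- 0L; completed <- TRUE
  for (tr in seq_len(n_trials)) {
    remaining <- step_cap - total
    if (remaining <= 0) { completed <- FALSE; break }
    res <- elab_trial_core(env, params, values,
                           manipulation_factor(manipulation, tr), remaining)
    values <- res$values
    total <- total + res$steps
    steps_v[tr] <- res$steps
    reward_v[tr] <- sum(res$reward)
    dsum_v[tr] <- sum(res$delta)
    lat_v[tr] <- match(env$junction, res$state)
    hit <- which(res$action %in% env$arm_actions)
    if (length(hit))
      arm_v[tr] <- match(res$action[[hit[1L]]], env$arm_actions)
    if (record_steps)
      logs[[tr]] <- data.frame(trial = tr, t = seq_len(res$steps),
                               state = res$state, action = res$action,
                               delta = res$delta, reward = res$reward,
                               disp = res$disp)
    if (res$runaway) { completed <- FALSE; break }
    done <- tr
  }
  keep <- seq_len(if (completed) n_trials else done + 1L)
  keep <- keep[keep <= n_trials & steps_v[keep] > 0L]
  trials <- data.frame(trial = keep, steps = steps_v[keep],
                       reward = reward_v[keep], delta_sum = dsum_v[keep],
                       latency = lat_v[keep], arm = arm_v[keep])
  structure(
    list(trials = trials,
         steps = if (record_steps) do.call(rbind, logs[keep]) else NULL,
         values = stats::setNames(values, env$act_label),
         completed = completed, total_steps = total,
         seed = as.integer(seed), params = params, env_kind = env$kind,
         manipulation = manipulation, step_cap = step_cap,
         delta_by_action = NULL),
    class = "session_result"
  )
}

#' Velocity profile by internal state
#'
#' Mean displacement (the "velocity": displacement from the previous time
#' step) when the subject reached or stayed in each internal state, across
#' sessions: overall, and restricted to steps where the internal state
#' repeats (same state at the previous and current step within a trial).
#' Because location and state are only loosely coupled the subject can still
#' move while its internal state repeats, except at true stopping points
#' (start, junction, end).
#'
#' @param sessions List of elaborated-T-maze `session_result` objects run
#'   with `record_steps = TRUE`.
#' @return Data frame `state`, `mean_v`, `se_v`, `mean_v_same`, `se_v_same`
#'   (the `same` columns are `NA` for states never repeated).
#' @export
velocity_profile <- function(sessions) {
  if (inherits(sessions, "session_result")) sessions <- list(sessions)
  stopifnot(length(sessions) > 0,
            all(vapply(sessions, function(s) !is.null(s$steps), logical(1))))
  n_states <- max(vapply(sessions, function(s) max(s$steps$state),
                         numeric(1)))
  per <- function(s, same_only) {
    d <- s$steps
    prev_state <- c(NA_integer_, d$state[-nrow(d)])
    prev_trial <- c(NA_integer_, d$trial[-nrow(d)])
    same <- !is.na(prev_state) & prev_state == d$state &
      prev_trial == d$trial
    sel <- !is.na(d$disp) & (if (same_only) same else TRUE)
    vapply(seq_len(n_states), function(st) {
      v <- d$disp[sel & d$state == st]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  all_m <- vapply(sessions, per, numeric(n_states), same_only = FALSE)
  same_m <- vapply(sessions, per, numeric(n_states), same_only = TRUE)
  all_m <- matrix(all_m, nrow = n_states)
  same_m <- matrix(same_m, nrow = n_states)
  data.frame(
    state = seq_len(n_states),
    mean_v = rowMeans(all_m, na.rm = TRUE),
    se_v = apply(all_m, 1L, se_or_zero),
    mean_v_same = rowMeans(same_m, na.rm = TRUE),
    se_v_same = apply(same_m, 1L, se_or_zero)
  )
}
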