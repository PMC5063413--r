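#' Linear-track environment
#'
#' A self-paced goal-reaching task on a chain of `n_states` states
#' `S1 ... Sn`. At each pre-goal state the agent chooses `Stay` (remain in
#' place) or `Go` (advance one state); reaching the goal `Sn` delivers
#' `goal_reward` and ends the trial, after which the agent is automatically
#' returned to `S1` (the return consumes no time step). Action indices follow
#' the convention that odd indices are `Stay` and even indices are `Go`:
#' at state `Si` the `Stay` action has index `2i - 1` and `Go` has `2i`.
#'
#' Optionally a small reward `mid_reward` is delivered at `S4` at *every*
#' time step the agent occupies `S4` (a perturbation that can trap a
#' forgetting agent into persistent staying), and a `Back` action (move to
#' `S(i-1)`) can be added at the interior states `S2 ... S(n-1)`; `Back`
#' actions are indexed after all `Stay`/`Go` actions.
#'
#' @param n_states Number of states including start and goal (`>= 2`).
#' @param goal_reward Reward `r` delivered at the goal. Default 1.
#' @param mid_reward Reward `x >= 0` delivered at `S4` on every occupancy
#'   step. Requires `n_states >= 5` so that `S4` is not the goal. Default 0.
#' @param allow_back If `TRUE`, add a `Back` action at `S2 ... S(n-1)`.
#'
#' @return An environment object of class `c("linear_track", "rlenv")`.
#' @examples
#' env <- linear_track()
#' candidates(env, 3)
#' @export
linear_track <- function(n_states = 7L, goal_reward = 1, mid_reward = 0,
                         allow_back = FALSE) {
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 2L, goal_reward > 0, mid_reward >= 0)
  if (mid_reward > 0 && n_states < 5L)
    stop("mid_reward requires n_states >= 5 (S4 must precede the goal)")
  n_fwd <- 2L * (n_states - 1L)
  labels <- character(n_fwd)
  nxt <- integer(n_fwd)
  act_state <- integer(n_fwd)
  act_type <- character(n_fwd)
  for (i in seq_len(n_states - 1L)) {
    s_id <- 2L * i - 1L; g_id <- 2L * i
    labels[s_id] <- sprintf("Stay@S%d", i); labels[g_id] <- sprintf("Go@S%d", i)
    nxt[s_id] <- i; nxt[g_id] <- i + 1L
    act_state[c(s_id, g_id)] <- i
    act_type[s_id] <- "stay"; act_type[g_id] <- "go"
  }
  cand <- vector("list", n_states)
  for (i in seq_len(n_states - 1L)) cand[[i]] <- c(2L * i - 1L, 2L * i)
  cand[[n_states]] <- integer(0)
  if (allow_back && n_states >= 3L) {
    for (i in 2:(n_states - 1L)) {
      id <- length(nxt) + 1L
      labels[id] <- sprintf("Back@S%d", i)
      nxt[id] <- i - 1L
      act_state[id] <- i
      act_type[id] <- "back"
      cand[[i]] <- c(cand[[i]], id)
    }
  }
  occ_reward <- numeric(n_states)
  occ_reward[n_states] <- goal_reward
  if (mid_reward > 0) occ_reward[4L] <- mid_reward
  structure(
    list(kind = "track", n_states = n_states, start = 1L,
         terminal = n_states, n_actions = length(nxt),
         cand = cand, nxt = nxt, act_state = act_state,
         act_type = act_type, act_label = labels,
         occ_reward = occ_reward, fv_reward = numeric(n_states),
         junction = NA_integer_, arm_actions = NULL,
         goal_reward = goal_reward, mid_reward = mid_reward,
         allow_back = allow_back, min_steps = n_states),
    class = c("linear_track", "rlenv")
  )
}

#' Cost-benefit T-maze environment
#'
#' A nine-state T-maze. The agent starts in State 1, traverses the stem
#' (1 -> 2 -> 3) to the T-junction (State 4), where three actions are
#' available: go to Arm 1, go to Arm 2, or stay. Arm 1 runs 4 -> 5 -> 7 and
#' Arm 2 runs 4 -> 6 -> 8; `Go` at State 7 or 8 reaches the trial-end State 9,
#' which has no action and returns the agent to State 1 at the next trial.
#' All non-junction, non-end states offer `Go` and `Stay`.
#'
#' Rewards are delivered on the *first* arrival at a reward state within a
#' trial (at most once per state per trial). With `high_cost = TRUE` the
#' large reward (`reward_large`) sits at State 7, so Arm 1 carries an extra
#' state (State 5) before its reward, representing the high cost; the small
#' reward (`reward_small`) is at State 6, adjacent to the junction. With
#' `high_cost = FALSE` the large and small rewards sit at States 5 and 6
#' respectively, both one `Go` beyond the junction, so neither arm is costly.
#'
#' @param high_cost If `TRUE`, the large-reward arm carries a high cost
#'   (extra pre-reward state); if `FALSE`, neither arm does.
#' @param reward_large Reward of Arm 1 (default 1).
#' @param reward_small Reward of Arm 2 (default 0.5).
#'
#' @return An environment object of class `c("tmaze", "rlenv")`.
#' @examples
#' env <- tmaze(high_cost = TRUE)
#' candidates(env, 4)
#' @export
tmaze <- function(high_cost = TRUE, reward_large = 1, reward_small = 0.5) {
  stopifnot(reward_large > 0, reward_small > 0)
  n_states <- 9L
  labels <- character(0); nxt <- integer(0)
  act_state <- integer(0); act_type <- character(0)
  cand <- vector("list", n_states)
  add <- function(label, state, to, type) {
    id <- length(nxt) + 1L
    labels[id] <<- label; nxt[id] <<- to
    act_state[id] <<- state; act_type[id] <<- type
    cand[[state]] <<- c(cand[[state]], id)
    id
  }
  for (i in 1:3) {
    add(sprintf("Stay@S%d", i), i, i, "stay")
    add(sprintf("Go@S%d", i), i, i + 1L, "go")
  }
  add("Stay@S4", 4L, 4L, "stay")
  arm1 <- add("GoArm1@S4", 4L, 5L, "go")
  arm2 <- add("GoArm2@S4", 4L, 6L, "go")
  add("Stay@S5", 5L, 5L, "stay"); add("Go@S5", 5L, 7L, "go")
  add("Stay@S6", 6L, 6L, "stay"); add("Go@S6", 6L, 8L, "go")
  add("Stay@S7", 7L, 7L, "stay"); add("Go@S7", 7L, 9L, "go")
  add("Stay@S8", 8L, 8L, "stay"); add("Go@S8", 8L, 9L, "go")
  cand[[9L]] <- integer(0)
  fv <- numeric(n_states)
  if (high_cost) {
    fv[7L] <- reward_large  # large reward behind the extra state 5
    fv[6L] <- reward_small
  } else {
    fv[5L] <- reward_large
    fv[6L] <- reward_small
  }
  structure(
    list(kind = "tmaze", n_states = n_states, start = 1L, terminal = 9L,
         n_actions = length(nxt), cand = cand, nxt = nxt,
         act_state = act_state, act_type = act_type, act_label = labels,
         occ_reward = numeric(n_states), fv_reward = fv,
         junction = 4L, arm_actions = c(arm1, arm2),
         high_cost = high_cost, reward_large = reward_large,
         reward_small = reward_small, min_steps_junction = 4L),
    class = c("tmaze", "rlenv")
  )
}

#' Candidate actions at a state
#'
#' Returns the identifiers of the actions available at `state`. The goal /
#' trial-end state has no candidates (an empty integer vector): there the
#' trial ends and the agent is automatically returned to the start.
#'
#' @param env An `rlenv` environment.
#' @param state State identifier.
#' @return Named integer vector of action ids (possibly empty).
#' @examples
#' candidates(linear_track(), 7)   # goal: no candidates
#' @export
candidates <- function(env, state) {
  check_state(env, state)
  ids <- env$cand[[state]]
  stats::setNames(ids, env$act_label[ids])
}

#' Deterministic state transition
#'
#' @param env An `rlenv` environment.
#' @param state State identifier.
#' @param action Action identifier; must be a candidate at `state`.
#' @return The successor state id.
#' @examples
#' transition(linear_track(), 3, 6)  # Go at S3 -> S4
#' @export
transition <- function(env, state, action) {
  check_state(env, state)
  if (!is.numeric(action) || length(action) != 1L ||
      !(action %in% env$cand[[state]]))
    stop(sprintf("action %s is not available at state %s",
                 format(action), format(state)))
  env$nxt[[action]]
}

#' Reward delivered at a state occupancy
#'
#' Per-occupancy rewards (the track's goal reward and any mid-track reward)
#' are delivered every time step spent at the state; first-visit rewards
#' (the T-maze arm rewards) only on the first arrival within a trial, as
#' indicated by `first_visit`.
#'
#' @param env An `rlenv` environment.
#' @param state State identifier.
#' @param first_visit Is this the first occupancy of `state` in the trial?
#' @return Reward (numeric scalar).
#' @examples
#' state_reward(tmaze(), 6, first_visit = TRUE)
#' @export
state_reward <- function(env, state, first_visit = TRUE) {
  check_state(env, state)
  env$occ_reward[state] + if (first_visit) env$fv_reward[state] else 0
}

#' Export an environment's transition graph as an edge list
#'
#' @param env An `rlenv` environment.
#' @return A data frame with one row per action: `action`, `label`, `from`,
#'   `to`, `type`.
#' @export
env_edge_list <- function(env) {
  stopifnot(inherits(env, "rlenv"))
  data.frame(action = seq_len(env$n_actions), label = env$act_label,
             from = env$act_state, to = env$nxt, type = env$act_type,
             stringsAsFactors = FALSE)
}

check_state <- function(env, state) {
  stopifnot(inherits(env, "rlenv"))
  if (!is.numeric(state) || length(state) != 1L || is.na(state) ||
      state < 1 || state > env$n_states || state != as.integer(state))
    stop(sprintf("invalid state id: %s", format(state)))
  invisible(TRUE)
}

#' @export
print.rlenv <- function(x, ...) {
  cat(sprintf("<rlenv:%s> %d states, %d actions\n",
              x$kind, x$n_states, x$n_actions))
  invisible(x)
}
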