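#' State-value TD error
#'
#' RPE of the state-value model variant:
#' `delta = reward + gamma * V(next_state) - V(state)`. When `state` is the
#' goal there is no successor and the future term is replaced by 0 (pass
#' `next_state = NA`).
#'
#' @param values State-value table (numeric vector indexed by state).
#' @param state Current state id.
#' @param next_state Successor state id, or `NA` at the goal.
#' @param reward Reward at the current state.
#' @param gamma Time discount factor.
#' @return The RPE `delta`.
#' @examples
#' td_error_state(c(0.4, 0.6), 1, 2, reward = 0, gamma = 1)
#' @export
td_error_state <- function(values, state, next_state, reward, gamma = 1) {
  s <- check_action_id(values, state, allow_none = FALSE)
  nx <- check_action_id(values, next_state)
  future <- if (nx > 0L) values[[nx]] else 0
  reward + gamma * future - values[[s]]
}

#' State-value update
#'
#' Adds `alpha * factor * delta` to `V(state)` only.
#'
#' @inheritParams td_error_state
#' @param delta RPE.
#' @param alpha Learning rate.
#' @param factor Blockade scaling of the increment (default 1).
#' @return Updated state-value table.
#' @export
update_state <- function(values, state, delta, alpha, factor = 1) {
  s <- check_action_id(values, state, allow_none = FALSE)
  values[[s]] <- values[[s]] + alpha * factor * delta
  values
}

#' State-value decay
#'
#' Multiplies every state value by `1 - phi`.
#'
#' @inheritParams td_error_state
#' @param phi Decay rate.
#' @return Decayed state-value table.
#' @export
decay_state <- function(values, phi) apply_decay(values, phi)

#' Probability of choosing `Go` under state-value selection
#'
#' `Go` from `Si` to `S(i+1)` is chosen with probability
#' `exp(beta * V(S_{i+1})) / (exp(beta * V(S_i)) + exp(beta * V(S_{i+1})))`,
#' computed in overflow-safe form.
#'
#' @param values State-value table.
#' @param state_i Current state id.
#' @param state_next Successor state id.
#' @param beta Inverse temperature.
#' @return Probability in (0, 1).
#' @examples
#' go_prob_state(c(0.2, 0.4), 1, 2, beta = 5)
#' @export
go_prob_state <- function(values, state_i, state_next, beta) {
  i <- check_action_id(values, state_i, allow_none = FALSE)
  j <- check_action_id(values, state_next, allow_none = FALSE)
  stats::plogis(beta * (values[[j]] - values[[i]]))
}

#' Run a session of the state-value model on the linear track
#'
#' Variant agent without action values: selection between `Go` and `Stay` at
#' every pre-goal state (including the start) compares the values of the
#' current and next state, and learning updates `V(S)` with the same
#' update-then-decay ordering per counted time step as the action-value
#' agent.
#'
#' @param env A [linear_track()] environment (without `Back` actions).
#' @param params An [agent_params()] object (`algorithm` is ignored; the
#'   state-value RPE has a single form).
#' @param n_trials Number of trials.
#' @param seed RNG seed.
#' @param manipulation Optional [da_manipulation()].
#' @param step_cap Cumulative step budget.
#' @return A `session_result` whose `values` element is the state-value
#'   table `V(S1) ... V(Sn)`.
#' @examples
#' s <- run_session_state(linear_track(), agent_params(phi = 0.01),
#'                        n_trials = 50, seed = 1)
#' s$values
#' @export
run_session_state <- function(env, params, n_trials, seed,
                              manipulation = NULL, step_cap = Inf) {
  stopifnot(inherits(env, "linear_track"), inherits(params, "agent_params"),
            !env$allow_back, n_trials >= 1)
  n_trials <- as.integer(n_trials)
  set.seed(as.integer(seed))
  n <- env$n_states
  v <- numeric(n)
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  keep <- 1 - params$phi
  occ <- env$occ_reward
  steps_v <- integer(n_trials); reward_v <- numeric(n_trials)
  dsum_v <- numeric(n_trials)
  total <- 0L
  completed <- TRUE
  done <- 0L
  for (tr in seq_len(n_trials)) {
    factor <- manipulation_factor(manipulation, tr)
    state <- 1L
    t <- 0L
    rtot <- 0; dtot <- 0
    runaway <- FALSE
    repeat {
      if (total + t >= step_cap) { runaway <- TRUE; break }
      t <- t + 1L
      r <- occ[[state]]
      rtot <- rtot + r
      if (state == n) {
        delta <- r - v[[state]]
        dtot <- dtot + delta
        v[[state]] <- v[[state]] + alpha * factor * delta
        v <- v * keep
        break
      }
      go <- stats::runif(1) < stats::plogis(beta * (v[[state + 1L]] - v[[state]]))
      nxt <- if (go) state + 1L else state
      delta <- r + gamma * v[[nxt]] - v[[state]]
      dtot <- dtot + delta
      v[[state]] <- v[[state]] + alpha * factor * delta
      v <- v * keep
      state <- nxt
    }
    total <- total + t
    steps_v[tr] <- t; reward_v[tr] <- rtot; dsum_v[tr] <- dtot
    if (runaway) { completed <- FALSE; break }
    done <- tr
  }
  kept <- seq_len(if (completed) n_trials else done + 1L)
  kept <- kept[kept <= n_trials & steps_v[kept] > 0L]
  structure(
    list(trials = data.frame(trial = kept, steps = steps_v[kept],
                             reward = reward_v[kept],
                             delta_sum = dsum_v[kept]),
         steps = NULL,
         values = stats::setNames(v, paste0("S", seq_len(n))),
         completed = completed, total_steps = total,
         seed = as.integer(seed), params = params,
         env_kind = "track_state_value", manipulation = manipulation,
         step_cap = step_cap, delta_by_action = NULL),
    class = "session_result"
  )
}
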