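#' Asymptotic value under persistent staying
#'
#' If the agent keeps choosing `Stay` at a state delivering `reward` on every
#' occupancy step, the update-then-decay iteration for that action's value is
#' `V <- (1 - phi) * (V + alpha * delta)` with
#' `delta = reward + gamma * V - V` (with `gamma = 1` the value terms cancel
#' and `delta = reward` every step). This returns the fixed point, either by
#' iterating from `V = 0` to convergence or, with `closed_form = TRUE`, by
#' solving the fixed-point equation directly. Both routes agree to `tol`.
#'
#' With `reward = 0.1`, `alpha = 0.5`: `phi = 0.01`, `gamma = 1` gives
#' `V = 4.95`; `phi = 0`, `gamma = 0.9` gives `V = 1`.
#'
#' @param reward Per-step reward at the occupied state.
#' @param alpha Learning rate.
#' @param phi Decay rate.
#' @param gamma Time discount factor.
#' @param tol Convergence tolerance of the iteration.
#' @param closed_form Solve the linear fixed-point equation instead of
#'   iterating.
#' @return The asymptotic value (numeric scalar).
#' @examples
#' persistent_stay_value(0.1, alpha = 0.5, phi = 0.01, gamma = 1)  # 4.95
#' @export
persistent_stay_value <- function(reward, alpha = 0.5, phi = 0.01,
                                  gamma = 1, tol = 1e-12,
                                  closed_form = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, phi >= 0, phi < 1,
            gamma >= 0, gamma <= 1)
  # V* = (1-phi)(V* + alpha(reward + (gamma-1)V*))
  a <- (1 - phi) * (1 + alpha * (gamma - 1))
  b <- (1 - phi) * alpha * reward
  if (a >= 1) stop("no finite fixed point: the value grows without bound")
  if (closed_form) return(b / (1 - a))
  v <- 0
  repeat {
    v_new <- a * v + b
    if (abs(v_new - v) < tol) return(v_new)
    v <- v_new
  }
}

#' Converged greedy `Go` value on the track without forgetting
#'
#' With `phi = 0`, once the agent reliably runs to the goal the value of `Go`
#' at `Si` converges to `gamma^(n_states - 1 - i) * goal_reward`: the goal
#' reward discounted by the number of remaining transitions. E.g. with
#' `gamma = 0.9` on the 7-state track, `Go` at `S4` converges to
#' `0.9^2 = 0.81`.
#'
#' @param state_index Index `i` of the state (`1 <= i <= n_states - 1`).
#' @param n_states Number of track states.
#' @param goal_reward Reward at the goal.
#' @param gamma Time discount factor.
#' @return The converged `Go` value.
#' @examples
#' asymptotic_go_value(4, gamma = 0.9)  # 0.81
#' @export
asymptotic_go_value <- function(state_index, n_states = 7L, goal_reward = 1,
                                gamma = 1) {
  stopifnot(state_index >= 1, state_index <= n_states - 1)
  gamma^(n_states - 1 - state_index) * goal_reward
}

#' Break-even mid-track reward
#'
#' On the track, staying forever at the mid-track reward state earns
#' `x` per step while the fastest goal-reaching earns
#' `(x + goal_reward) / n_states` per step (one mid-track delivery plus the
#' goal reward per `n_states`-step trial). Persistent staying becomes
#' advantageous above the break-even size `x*` solving
#' `n_states * x = x + goal_reward`, i.e.
#' `x* = goal_reward / (n_states - 1)` (about 0.1667 for 7 states and unit
#' reward).
#'
#' @param n_states Number of track states.
#' @param goal_reward Reward at the goal.
#' @return The break-even mid-track reward size.
#' @examples
#' breakeven_mid_reward()  # 1/6
#' @export
breakeven_mid_reward <- function(n_states = 7L, goal_reward = 1) {
  stopifnot(n_states >= 2)
  goal_reward / (n_states - 1)
}
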