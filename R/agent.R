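#' Initial value table for an environment
#'
#' All learned action values start at 0.
#'
#' @param env An `rlenv` environment.
#' @return Named numeric vector with one entry per action.
#' @export
value_table <- function(env) {
  stopifnot(inherits(env, "rlenv"))
  stats::setNames(numeric(env$n_actions), env$act_label)
}

check_action_id <- function(values, action, allow_none = TRUE) {
  if (is.null(action) || (length(action) == 1L && is.na(action))) {
    if (allow_none) return(0L)
    stop("an action id is required here")
  }
  if (!is.numeric(action) || length(action) != 1L ||
      action < 1 || action > length(values) || action != as.integer(action))
    stop(sprintf("unknown action id: %s", format(action)))
  as.integer(action)
}

#' Q-learning reward-prediction error
#'
#' Computes `delta = reward + gamma * max(Q(candidates)) - Q(prev_action)`.
#' At the goal there are no candidate actions and the future-value term is
#' replaced by 0; at the beginning of a trial there is no previous action and
#' `Q(prev_action)` is replaced by 0 (the start of a trial is not
#' predictable).
#'
#' @param values Value table (named numeric vector).
#' @param prev_action Id of the action taken at the previous time step, or
#'   `NA`/`NULL` at the start of a trial.
#' @param candidates Integer vector of candidate action ids at the current
#'   state (empty at the goal).
#' @param reward Reward obtained at the current state.
#' @param gamma Time discount factor.
#' @return The RPE `delta` (numeric scalar).
#' @examples
#' q <- c(Stay = 0.2, Go = 0.6)
#' td_error_q(q, prev_action = NA, candidates = 1:2, reward = 0, gamma = 1)
#' @export
td_error_q <- function(values, prev_action, candidates, reward, gamma = 1) {
  prev <- check_action_id(values, prev_action)
  if (length(candidates)) {
    candidates <- vapply(candidates, function(a)
      check_action_id(values, a, allow_none = FALSE), integer(1))
    future <- max(values[candidates])
  } else future <- 0
  prevq <- if (prev > 0L) values[[prev]] else 0
  reward + gamma * future - prevq
}

#' SARSA reward-prediction error
#'
#' Computes `delta = reward + gamma * Q(cur_action) - Q(prev_action)`, using
#' the value of the action actually selected at the current state rather than
#' the maximum candidate value. The boundary conventions mirror Q-learning:
#' at the goal no current action exists and the future term is 0; at the
#' trial start `Q(prev_action)` is 0. Under SARSA the current action must be
#' selected *before* the RPE is computed.
#'
#' @inheritParams td_error_q
#' @param cur_action Id of the action selected at the current state, or
#'   `NA`/`NULL` at the goal.
#' @return The RPE `delta` (numeric scalar).
#' @export
td_error_sarsa <- function(values, prev_action, cur_action, reward,
                           gamma = 1) {
  prev <- check_action_id(values, prev_action)
  cur <- check_action_id(values, cur_action)
  future <- if (cur > 0L) values[[cur]] else 0
  prevq <- if (prev > 0L) values[[prev]] else 0
  reward + gamma * future - prevq
}

#' RPE-dependent value update
#'
#' Adds `alpha * blockade_factor * delta` to the value of `action`, leaving
#' every other entry untouched. `blockade_factor` models dopamine blockade:
#' 1 is the unmanipulated update, 0.25 partial and 0 complete blockade.
#'
#' @param values Value table.
#' @param action Id of the action to update.
#' @param delta RPE.
#' @param alpha Learning rate.
#' @param blockade_factor Scaling of the increment, in `[0, 1]`.
#' @return The updated value table.
#' @examples
#' apply_update(c(a = 0.4), 1, delta = 0.2, alpha = 0.5)
#' @export
apply_update <- function(values, action, delta, alpha,
                         blockade_factor = 1) {
  a <- check_action_id(values, action, allow_none = FALSE)
  stopifnot(blockade_factor >= 0, blockade_factor <= 1)
  values[[a]] <- values[[a]] + alpha * blockade_factor * delta
  values
}

#' Multiplicative value decay (forgetting)
#'
#' Multiplies *every* learned value by `1 - phi`, selected or not. Applied
#' once per counted time step.
#'
#' @param values Value table (action or state values).
#' @param phi Decay rate in `[0, 1]`.
#' @return The decayed value table.
#' @examples
#' apply_decay(c(a = 1, b = 0.5), phi = 0.01)
#' @export
apply_decay <- function(values, phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0, phi <= 1)
  values * (1 - phi)
}

#' Softmax choice probabilities
#'
#' `P(a_i) = exp(beta * q_i) / sum_j exp(beta * q_j)`, computed
#' shift-invariantly (the maximum is subtracted before exponentiation) so
#' that large `beta` does not overflow.
#'
#' @param action_values Numeric vector of values (length >= 1).
#' @param beta Inverse temperature, `>= 0`.
#' @return Vector of probabilities summing to 1.
#' @examples
#' softmax_probs(c(0.2, 0.4), beta = 5)
#' @export
softmax_probs <- function(action_values, beta) {
  if (!length(action_values)) stop("action_values must be non-empty")
  stopifnot(is.numeric(action_values), is.numeric(beta), beta >= 0)
  w <- exp(beta * (action_values - max(action_values)))
  w / sum(w)
}

# Sample an index from softmax probabilities; uses the session RNG stream.
softmax_pick <- function(q, beta) {
  n <- length(q)
  if (n == 1L) return(1L)
  w <- exp(beta * (q - max(q)))
  u <- stats::runif(1) * sum(w)
  cs <- w[[1L]]
  i <- 1L
  while (cs < u && i < n) {
    i <- i + 1L
    cs <- cs + w[[i]]
  }
  i
}

# Fast inner loop shared by run_trial()/run_session(). Per counted time step:
# arrive -> collect reward -> (SARSA: select action) -> compute raw delta ->
# update Q(prev) with the blockade-scaled increment -> decay all values ->
# (Q-learning: select action) -> move. Returns raw per-step logs as vectors.
trial_core <- function(env, params, values, factor, max_steps) {
  cand <- env$cand; nxt <- env$nxt
  occ <- env$occ_reward; fv <- env$fv_reward
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  keep <- 1 - params$phi
  sarsa <- params$algorithm == "sarsa"
  state <- env$start
  prev <- 0L
  seen <- logical(env$n_states)
  cap <- 64L
  st_v <- integer(cap); ac_v <- integer(cap)
  de_v <- numeric(cap); rw_v <- numeric(cap)
  t <- 0L
  runaway <- FALSE
  repeat {
    if (t >= max_steps) { runaway <- TRUE; break }
    t <- t + 1L
    if (t > cap) {
      cap <- cap * 2L
      length(st_v) <- cap; length(ac_v) <- cap
      length(de_v) <- cap; length(rw_v) <- cap
    }
    r <- occ[[state]]
    if (fv[[state]] != 0 && !seen[[state]]) {
      r <- r + fv[[state]]
      seen[[state]] <- TRUE
    }
    cd <- cand[[state]]
    nc <- length(cd)
    a_cur <- 0L
    if (nc > 0L && sarsa) a_cur <- cd[[softmax_pick(values[cd], beta)]]
    future <- if (nc == 0L) 0 else if (sarsa) values[[a_cur]] else
      max(values[cd])
    delta <- r + gamma * future - (if (prev > 0L) values[[prev]] else 0)
    st_v[t] <- state; de_v[t] <- delta; rw_v[t] <- r
    if (prev > 0L)
      values[[prev]] <- values[[prev]] + alpha * factor * delta
    values <- values * keep
    if (nc == 0L) { ac_v[t] <- NA_integer_; break }
    if (!sarsa) a_cur <- cd[[softmax_pick(values[cd], beta)]]
    ac_v[t] <- a_cur
    prev <- a_cur
    state <- nxt[[a_cur]]
  }
  idx <- seq_len(t)
  list(steps = t, values = values, runaway = runaway,
       state = st_v[idx], action = ac_v[idx],
       delta = de_v[idx], reward = rw_v[idx])
}

#' Run a single trial
#'
#' Simulates one trial from the environment's start state until the goal /
#' trial-end state is reached (or `max_steps` is exhausted, which flags the
#' trial as a runaway). The step count includes the steps at the start and at
#' the goal; the decay is applied exactly once per counted time step to all
#' values. Logged RPEs are the raw `delta` values, before any blockade
#' scaling. Uses the current RNG state; seed it (or use [run_session()]) for
#' reproducibility.
#'
#' @param env An `rlenv` environment.
#' @param params An [agent_params()] object.
#' @param values Value table; defaults to all zeros.
#' @param manipulation Optional [da_manipulation()].
#' @param trial_index Trial index, used to decide whether the manipulation is
#'   active (`trial_index > onset_trial`).
#' @param max_steps Per-trial step budget; exceeding it aborts the trial with
#'   `runaway = TRUE`.
#' @return A list with `steps`, the updated `values`, `runaway`, and a
#'   `records` data frame (`t`, `state`, `action`, `delta`, `reward`; the
#'   goal step has `action = NA`).
#' @examples
#' set.seed(1)
#' run_trial(linear_track(), agent_params(phi = 0.01))$steps
#' @export
run_trial <- function(env, params, values = value_table(env),
                      manipulation = NULL, trial_index = 1L,
                      max_steps = Inf) {
  stopifnot(inherits(env, "rlenv"), inherits(params, "agent_params"),
            length(values) == env$n_actions)
  res <- trial_core(env, params, as.numeric(values),
                    manipulation_factor(manipulation, trial_index),
                    max_steps)
  list(
    steps = res$steps,
    values = stats::setNames(res$values, env$act_label),
    runaway = res$runaway,
    records = data.frame(t = seq_len(res$steps), state = res$state,
                         action = res$action, delta = res$delta,
                         reward = res$reward)
  )
}

#' Run a session of trials
#'
#' Runs `n_trials` consecutive trials with a single seeded RNG stream,
#' carrying the value table across trials. The automatic return from the
#' goal to the start consumes no time step and triggers no extra decay.
#' An optional `step_cap` bounds the *cumulative* number of time steps in
#' the session; if it is exhausted (e.g. because the agent settles into
#' persistent staying at a mid-track reward) the session stops with
#' `completed = FALSE`.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials (`>= 1`).
#' @param seed Integer seed for the session's RNG stream.
#' @param step_cap Cumulative step budget for the whole session (default
#'   `Inf`).
#' @param record_steps Keep the full per-step log? (Per-trial summaries are
#'   always kept.)
#' @return An object of class `session_result`: a list with
#'   \describe{
#'     \item{trials}{data frame `trial`, `steps`, `reward`, `delta_sum`,
#'       plus `latency` (steps from start through first junction occupancy)
#'       and `arm` (1/2) for T-maze environments}
#'     \item{steps}{per-step log data frame, or `NULL`}
#'     \item{values}{final value table}
#'     \item{completed}{did all `n_trials` finish within `step_cap`?}
#'     \item{total_steps, seed, params, env_kind, manipulation, step_cap}{run
#'       metadata}
#'     \item{delta_by_action}{data frame of summed raw RPE and step counts,
#'       split by action type (`go`/`stay`/`back`/`none`)}
#'   }
#' @examples
#' s <- run_session(linear_track(), agent_params(phi = 0.01),
#'                  n_trials = 50, seed = 1)
#' mean(s$trials$steps)
#' @export
run_session <- function(env, params, n_trials, seed,
                        manipulation = NULL, step_cap = Inf,
                        record_steps = FALSE, values = value_table(env)) {
  stopifnot(inherits(env, "rlenv"), inherits(params, "agent_params"),
            n_trials >= 1)
  n_trials <- as.integer(n_trials)
  set.seed(as.integer(seed))
  values <- as.numeric(values)
  is_tmaze <- !is.na(env$junction)
  steps_v <- integer(n_trials); reward_v <- numeric(n_trials)
  dsum_v <- numeric(n_trials)
  lat_v <- rep(NA_integer_, n_trials); arm_v <- rep(NA_integer_, n_trials)
  types <- c("go", "stay", "back", "none")
  d_sum <- stats::setNames(numeric(4), types)
  d_n <- stats::setNames(integer(4), types)
  logs <- if (record_steps) vector("list", n_trials) else NULL
  total <- 0L
  done <- 0L
  completed <- TRUE
  for (tr in seq_len(n_trials)) {
    remaining <- step_cap - total
    if (remaining <= 0) { completed <- FALSE; break }
    res <- trial_core(env, params, values,
                      manipulation_factor(manipulation, tr), remaining)
    values <- res$values
    total <- total + res$steps
    steps_v[tr] <- res$steps
    reward_v[tr] <- sum(res$reward)
    dsum_v[tr] <- sum(res$delta)
    at <- ifelse(is.na(res$action), "none", env$act_type[res$action])
    for (ty in unique(at)) {
      sel <- at == ty
      d_sum[[ty]] <- d_sum[[ty]] + sum(res$delta[sel])
      d_n[[ty]] <- d_n[[ty]] + sum(sel)
    }
    if (is_tmaze) {
      lat_v[tr] <- match(env$junction, res$state)
      hit <- which(res$action %in% env$arm_actions)
      if (length(hit))
        arm_v[tr] <- match(res$action[[hit[1L]]], env$arm_actions)
    }
    if (record_steps)
      logs[[tr]] <- data.frame(trial = tr, t = seq_len(res$steps),
                               state = res$state, action = res$action,
                               delta = res$delta, reward = res$reward)
    if (res$runaway) { completed <- FALSE; break }
    done <- tr
  }
  keep <- seq_len(if (completed) n_trials else done + 1L)
  keep <- keep[keep <= n_trials & steps_v[keep] > 0L]
  trials <- data.frame(trial = keep, steps = steps_v[keep],
                       reward = reward_v[keep], delta_sum = dsum_v[keep])
  if (is_tmaze) {
    trials$latency <- lat_v[keep]
    trials$arm <- arm_v[keep]
  }
  structure(
    list(trials = trials,
         steps = if (record_steps) do.call(rbind, logs[keep]) else NULL,
         values = stats::setNames(values, env$act_label),
         completed = completed, total_steps = total,
         seed = as.integer(seed), params = params, env_kind = env$kind,
         manipulation = manipulation, step_cap = step_cap,
         delta_by_action = data.frame(type = types, delta_sum = d_sum,
                                      n_steps = as.integer(d_n),
                                      row.names = NULL)),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "<session_result:%s> %d trials, %d steps, completed=%s, seed=%d\n",
    x$env_kind, nrow(x$trials), x$total_steps, x$completed, x$seed))
  invisible(x)
}

#' Chance-level trial length on the linear track
#'
#' Expected number of time steps per trial (counting the start and goal
#' steps) when `Go` and `Stay` are each chosen with probability 1/2 at every
#' pre-goal state. Computed from the series over lattice paths with `k`
#' extra `Stay` steps distributed over the `n - 1` pre-goal states: the
#' number of such repeated combinations is `h(n-1, k) = choose(k + n - 2, k)`,
#' and the expectation is
#' `n + sum_k k * h(n-1, k) * (1/2)^(k + n - 1)`.
#' For the unbiased policy this equals `2 * n_states - 1` (13 for 7 states).
#'
#' @param n_states Number of states including start and goal (`>= 2`).
#' @param tol Truncation tolerance for the series.
#' @return Expected steps per trial (numeric scalar).
#' @examples
#' chance_level_steps(7)  # 13
#' @export
chance_level_steps <- function(n_states, tol = 1e-15) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 2 ||
      n_states != as.integer(n_states))
    stop("n_states must be a single integer >= 2")
  n <- as.integer(n_states)
  m <- n - 1L  # pre-goal states
  extra <- 0
  k <- 1
  repeat {
    term <- k * choose(k + m - 1, k) * 0.5^(k + m)
    extra <- extra + term
    if (term < tol && k > m) break
    k <- k + 1
  }
  n + extra
}

#' Summarize sessions
#'
#' Computes per-block mean trial lengths (mean +/- SE across sessions, where
#' the SE of a single session is 0 by convention) and the mean raw RPE per
#' time step.
#'
#' @param sessions A list of `session_result` objects sharing a
#'   configuration.
#' @param block Block size in trials (default 5).
#' @return A list of class `session_summary` with elements `blocks` (data
#'   frame `block`, `trial_lo`, `trial_hi`, `mean_steps`, `se_steps`),
#'   `mean_steps`, `se_steps`, `mean_delta_per_step`, `se_delta_per_step`,
#'   `n_sessions`.
#' @export
summarize_sessions <- function(sessions, block = 5L) {
  if (inherits(sessions, "session_result")) sessions <- list(sessions)
  if (!length(sessions)) stop("at least one session is required")
  stopifnot(all(vapply(sessions, inherits, logical(1), "session_result")))
  kinds <- unique(vapply(sessions, `[[`, character(1), "env_kind"))
  if (length(kinds) != 1L)
    stop("sessions mix different environments: ", paste(kinds, collapse = ", "))
  block <- as.integer(block)
  n_trials <- max(vapply(sessions, function(s) max(s$trials$trial), numeric(1)))
  edges <- seq(1L, n_trials, by = block)
  blocks <- data.frame(block = seq_along(edges), trial_lo = edges,
                       trial_hi = pmin(edges + block - 1L, n_trials))
  per <- vapply(sessions, function(s) {
    vapply(seq_len(nrow(blocks)), function(b) {
      sel <- s$trials$trial >= blocks$trial_lo[b] &
        s$trials$trial <= blocks$trial_hi[b]
      if (any(sel)) mean(s$trials$steps[sel]) else NA_real_
    }, numeric(1))
  }, numeric(nrow(blocks)))
  per <- matrix(per, nrow = nrow(blocks))
  blocks$mean_steps <- rowMeans(per, na.rm = TRUE)
  blocks$se_steps <- apply(per, 1L, se_or_zero)
  sess_steps <- vapply(sessions, function(s) mean(s$trials$steps), numeric(1))
  sess_delta <- vapply(sessions, function(s)
    sum(s$trials$delta_sum) / sum(s$trials$steps), numeric(1))
  structure(
    list(blocks = blocks, mean_steps = mean(sess_steps),
         se_steps = se_or_zero(sess_steps),
         mean_delta_per_step = mean(sess_delta),
         se_delta_per_step = se_or_zero(sess_delta),
         n_sessions = length(sessions), block = block),
    class = "session_summary"
  )
}

se_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) 0 else stats::sd(x) / sqrt(length(x))
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<session_summary> %d sessions: mean steps/trial %.3f ",
           "(SE %.3f), mean RPE/step %.4f (SE %.4f)\n"),
    x$n_sessions, x$mean_steps, x$se_steps,
    x$mean_delta_per_step, x$se_delta_per_step))
  invisible(x)
}

#' T-maze choice and latency metrics
#'
#' Per-block ratio of choosing Arm 1 and mean latency (number of time steps
#' from the trial start through the first occupancy of the T-junction,
#' inclusive; the theoretical minimum is 4), each as mean +/- SE across
#' sessions.
#'
#' @param sessions List of T-maze `session_result` objects.
#' @param block Block size in trials (default 10).
#' @return Data frame with `block`, `trial_lo`, `trial_hi`, `arm1_ratio`,
#'   `arm1_se`, `latency`, `latency_se`.
#' @export
tmaze_metrics <- function(sessions, block = 10L) {
  if (inherits(sessions, "session_result")) sessions <- list(sessions)
  stopifnot(length(sessions) > 0,
            all(vapply(sessions, function(s)
              "arm" %in% names(s$trials), logical(1))))
  block <- as.integer(block)
  n_trials <- max(vapply(sessions, function(s) max(s$trials$trial), numeric(1)))
  edges <- seq(1L, n_trials, by = block)
  out <- data.frame(block = seq_along(edges), trial_lo = edges,
                    trial_hi = pmin(edges + block - 1L, n_trials))
  stat <- function(f) {
    m <- vapply(sessions, function(s) {
      vapply(seq_len(nrow(out)), function(b) {
        sel <- s$trials$trial >= out$trial_lo[b] &
          s$trials$trial <= out$trial_hi[b]
        if (any(sel)) f(s$trials[sel, ]) else NA_real_
      }, numeric(1))
    }, numeric(nrow(out)))
    matrix(m, nrow = nrow(out))
  }
  ratio <- stat(function(d) mean(d$arm == 1L, na.rm = TRUE))
  lat <- stat(function(d) mean(d$latency, na.rm = TRUE))
  out$arm1_ratio <- rowMeans(ratio, na.rm = TRUE)
  out$arm1_se <- apply(ratio, 1L, se_or_zero)
  out$latency <- rowMeans(lat, na.rm = TRUE)
  out$latency_se <- apply(lat, 1L, se_or_zero)
  out
}
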