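#' Names of the built-in experiments
#'
#' @return Character vector of names accepted by [run_experiment()].
#' @export
experiment_names <- function() {
  c("decay_sweep", "blockade", "value_profiles", "tmaze", "state_value",
    "param_dependence", "reward_amount", "architecture", "mid_reward",
    "elaborated", "bifurcation")
}

n_scaled <- function(n, scale) max(1L, as.integer(round(n * scale)))

# 20 independently seeded sessions = 20 simulated subjects.
session_seeds <- function(base_seed, n) base_seed + seq_len(n) - 1L

run_batch <- function(env, params, n_sessions, n_trials, base_seed,
                      manipulation = NULL, step_cap = Inf) {
  lapply(session_seeds(base_seed, n_sessions), function(sd)
    run_session(env, params, n_trials, seed = sd,
                manipulation = manipulation, step_cap = step_cap))
}

#' Run a predefined simulation experiment
#'
#' Config-driven reproduction of the package's simulation experiments,
#' optionally at reduced scale. Each experiment runs a fixed recipe of
#' sessions (default 20 sessions of 500 trials; T-maze experiments use 1000
#' trials) over a parameter grid and returns summary tables; `scale` shrinks
#' the number of sessions and trials proportionally (changing only sampling
#' noise, not the configuration semantics). Results are deterministic given
#' `seed`: session seeds are derived as `seed + session_index - 1`.
#'
#' Available experiments:
#' \describe{
#'   \item{decay_sweep}{mean trial length vs decay rate `phi` in
#'     `seq(0, 0.02, 0.002)`, plus 5-trial block series for
#'     `phi = 0, 0.01, 0.02`.}
#'   \item{blockade}{post-training blockade (factor 0 and 0.25 after 250
#'     trials) for `phi = 0, 0.01, 0.02`; 5-trial block series.}
#'   \item{value_profiles}{final action values and RPE statistics for
#'     `phi = 0, 0.01, 0.02`.}
#'   \item{tmaze}{cost-benefit T-maze, both conditions, depletion (factor
#'     0.25) after half the trials; 10-trial-block arm-choice ratio and
#'     latency.}
#'   \item{state_value}{state-value model variant: trial length vs `phi`
#'     and final state values.}
#'   \item{param_dependence}{trial length vs `phi` while varying one of
#'     `alpha`, `beta`, `gamma`, for Q-learning and SARSA; plus mean RPE on
#'     Go vs Stay steps per algorithm.}
#'   \item{reward_amount}{goal rewards 0.5-1.5: trial length and mean
#'     RPE/step, with and without decay.}
#'   \item{architecture}{4- and 10-state tracks and the 7-state track with
#'     a `Back` action, over the `phi` grid.}
#'   \item{mid_reward}{per-occupancy reward `x` at `S4` (`x` in
#'     `seq(0, 0.1, 0.02)`), `phi = 0.01`, session step cap 35000:
#'     completion percentage and trial length of completing runs; plus
#'     discounted variants (`gamma = 0.9, 0.8`) at `x = 0.1`.}
#'   \item{elaborated}{kinematic T-maze, both conditions, depletion after
#'     half the trials: choice ratio, latency and velocity profiles.}
#'   \item{bifurcation}{reduced-model bifurcation diagram over `psi` and
#'     the upper saddle-node point.}
#' }
#'
#' @param name Experiment name (see [experiment_names()]).
#' @param scale Factor in (0, 1] applied to sessions and trials.
#' @param seed Base RNG seed.
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV together with a JSON manifest of the exact
#'   configuration run.
#' @return A named list of data frames (tables differ per experiment), with
#'   attribute `manifest`.
#' @examples
#' \donttest{
#' res <- run_experiment("decay_sweep", scale = 0.1, seed = 1)
#' res$phi_sweep
#' }
#' @export
run_experiment <- function(name, scale = 1, seed = 1L, out_dir = NULL) {
  name <- match.arg(name, experiment_names())
  stopifnot(scale > 0, scale <= 1)
  seed <- as.integer(seed)
  ns <- n_scaled(20L, scale)
  nt <- n_scaled(500L, scale)
  nt_tm <- n_scaled(1000L, scale)
  phi_grid <- seq(0, 0.02, by = 0.002)
  res <- switch(name,
    decay_sweep = {
      sweep <- do.call(rbind, lapply(phi_grid, function(phi) {
        sm <- summarize_sessions(run_batch(
          linear_track(), agent_params(phi = phi), ns, nt, seed))
        data.frame(phi = phi, mean_steps = sm$mean_steps,
                   se_steps = sm$se_steps)
      }))
      series <- do.call(rbind, lapply(c(0, 0.01, 0.02), function(phi) {
        sm <- summarize_sessions(run_batch(
          linear_track(), agent_params(phi = phi), ns, nt, seed), block = 5L)
        cbind(phi = phi, sm$blocks)
      }))
      list(phi_sweep = sweep, block_series = series)
    },
    blockade = {
      grid <- expand.grid(phi = c(0, 0.01, 0.02), factor = c(0, 0.25))
      onset <- n_scaled(250L, scale)
      series <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        man <- da_manipulation(grid$factor[i], onset)
        sm <- summarize_sessions(run_batch(
          linear_track(), agent_params(phi = grid$phi[i]), ns, nt, seed,
          manipulation = man), block = 5L)
        cbind(phi = grid$phi[i], factor = grid$factor[i],
              onset = onset, sm$blocks)
      }))
      list(block_series = series)
    },
    value_profiles = {
      vals <- do.call(rbind, lapply(c(0, 0.01, 0.02), function(phi) {
        sess <- run_batch(linear_track(), agent_params(phi = phi),
                          ns, nt, seed)
        vm <- sapply(sess, `[[`, "values")
        vm <- matrix(vm, ncol = length(sess))
        env <- linear_track()
        data.frame(phi = phi, action = seq_len(env$n_actions),
                   label = env$act_label, type = env$act_type,
                   mean_value = rowMeans(vm),
                   se_value = apply(vm, 1L, se_or_zero))
      }))
      list(final_values = vals)
    },
    tmaze = {
      onset <- n_scaled(500L, scale)
      out <- lapply(c(TRUE, FALSE), function(hc) {
        sess <- run_batch(tmaze(high_cost = hc), agent_params(phi = 0.01),
                          ns, nt_tm, seed,
                          manipulation = da_manipulation(0.25, onset))
        cbind(high_cost = hc, onset = onset,
              tmaze_metrics(sess, block = 10L))
      })
      list(metrics = do.call(rbind, out))
    },
    state_value = {
      sweep <- do.call(rbind, lapply(phi_grid, function(phi) {
        sess <- lapply(session_seeds(seed, ns), function(sd)
          run_session_state(linear_track(), agent_params(phi = phi),
                            nt, seed = sd))
        sm <- summarize_sessions(sess)
        data.frame(phi = phi, mean_steps = sm$mean_steps,
                   se_steps = sm$se_steps)
      }))
      vals <- do.call(rbind, lapply(c(0.01, 0.02), function(phi) {
        sess <- lapply(session_seeds(seed, ns), function(sd)
          run_session_state(linear_track(), agent_params(phi = phi),
                            nt, seed = sd))
        vm <- matrix(sapply(sess, `[[`, "values"), ncol = length(sess))
        data.frame(phi = phi, state = seq_len(nrow(vm)),
                   mean_value = rowMeans(vm),
                   se_value = apply(vm, 1L, se_or_zero))
      }))
      list(phi_sweep = sweep, final_state_values = vals)
    },
    param_dependence = {
      grids <- list(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    beta = c(1, 2, 5, 10),
                    gamma = c(0.7, 0.8, 0.9, 1))
      phis <- seq(0, 0.02, by = 0.004)
      sweep <- do.call(rbind, unlist(lapply(
        c("q_learning", "sarsa"), function(alg)
          lapply(names(grids), function(par)
            do.call(rbind, lapply(grids[[par]], function(v)
              do.call(rbind, lapply(phis, function(phi) {
                args <- list(phi = phi, algorithm = alg)
                args[[par]] <- v
                sm <- summarize_sessions(run_batch(
                  linear_track(), do.call(agent_params, args),
                  ns, nt, seed))
                data.frame(algorithm = alg, parameter = par, value = v,
                           phi = phi, mean_steps = sm$mean_steps,
                           se_steps = sm$se_steps)
              }))))), recursive = FALSE)))
      rpe <- do.call(rbind, lapply(c("q_learning", "sarsa"), function(alg) {
        sess <- run_batch(linear_track(),
                          agent_params(phi = 0.01, algorithm = alg),
                          ns, nt, seed)
        per <- sapply(sess, function(s) {
          d <- s$delta_by_action
          c(go = d$delta_sum[d$type == "go"] / d$n_steps[d$type == "go"],
            stay = d$delta_sum[d$type == "stay"] /
              d$n_steps[d$type == "stay"])
        })
        per <- matrix(per, nrow = 2)
        data.frame(algorithm = alg, action = c("go", "stay"),
                   mean_delta = rowMeans(per),
                   se_delta = apply(per, 1L, se_or_zero))
      }))
      list(param_sweep = sweep, rpe_by_action = rpe)
    },
    reward_amount = {
      grid <- expand.grid(r = c(0.5, 0.75, 1, 1.25, 1.5), phi = c(0, 0.01))
      tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        sm <- summarize_sessions(run_batch(
          linear_track(goal_reward = grid$r[i]),
          agent_params(phi = grid$phi[i]), ns, nt, seed))
        data.frame(r = grid$r[i], phi = grid$phi[i],
                   mean_steps = sm$mean_steps, se_steps = sm$se_steps,
                   mean_delta_per_step = sm$mean_delta_per_step,
                   se_delta_per_step = sm$se_delta_per_step)
      }))
      list(reward_sweep = tab)
    },
    architecture = {
      tab <- do.call(rbind, unlist(lapply(phi_grid, function(phi)
        lapply(list(list(n = 4L, back = FALSE), list(n = 10L, back = FALSE),
                    list(n = 7L, back = TRUE)), function(cfg) {
          sm <- summarize_sessions(run_batch(
            linear_track(n_states = cfg$n, allow_back = cfg$back),
            agent_params(phi = phi), ns, nt, seed))
          data.frame(n_states = cfg$n, allow_back = cfg$back, phi = phi,
                     mean_steps = sm$mean_steps, se_steps = sm$se_steps)
        })), recursive = FALSE))
      list(architecture_sweep = tab)
    },
    mid_reward = {
      cap <- n_scaled(35000L, scale)
      xs <- seq(0, 0.1, by = 0.02)
      tab <- do.call(rbind, lapply(xs, function(x) {
        sess <- run_batch(linear_track(mid_reward = x),
                          agent_params(phi = 0.01), ns, nt, seed,
                          step_cap = cap)
        comp <- vapply(sess, `[[`, logical(1), "completed")
        ok <- sess[comp]
        ms <- if (length(ok)) summarize_sessions(ok)$mean_steps else NA_real_
        se <- if (length(ok) > 1)
          se_or_zero(vapply(ok, function(s) mean(s$trials$steps),
                            numeric(1))) else 0
        data.frame(x = x, pct_completed = 100 * mean(comp),
                   mean_steps_completed = ms, se_steps_completed = se)
      }))
      disc <- do.call(rbind, unlist(lapply(c(0.9, 0.8), function(g)
        lapply(c(0, 0.01), function(phi) {
          sess <- run_batch(linear_track(mid_reward = 0.1),
                            agent_params(gamma = g, phi = phi),
                            ns, nt, seed, step_cap = cap)
          comp <- vapply(sess, `[[`, logical(1), "completed")
          data.frame(gamma = g, phi = phi,
                     pct_completed = 100 * mean(comp),
                     mean_steps = summarize_sessions(sess)$mean_steps)
        })), recursive = FALSE))
      list(completion = tab, discounted = disc)
    },
    elaborated = {
      onset <- n_scaled(500L, scale)
      out <- lapply(c(TRUE, FALSE), function(hc) {
        sess <- lapply(session_seeds(seed, ns), function(sd)
          run_session_elab(elaborated_tmaze(high_cost = hc),
                           agent_params(phi = 0.01), nt_tm, seed = sd,
                           manipulation = da_manipulation(0.25, onset)))
        list(metrics = cbind(high_cost = hc, onset = onset,
                             tmaze_metrics(sess, block = 10L)),
             velocity = cbind(high_cost = hc, velocity_profile(sess)))
      })
      list(metrics = rbind(out[[1]]$metrics, out[[2]]$metrics),
           velocity = rbind(out[[1]]$velocity, out[[2]]$velocity))
    },
    bifurcation = {
      step <- if (scale >= 1) 2e-4 else 2e-3
      diagram <- bifurcation_sweep(reduced_params(),
                                   seq(0, 0.12, by = step))
      psi_star <- find_saddle_node_upper(reduced_params())
      list(diagram = diagram,
           saddle_node = data.frame(psi_star = psi_star))
    }
  )
  manifest <- list(experiment = name, scale = scale, seed = seed,
                   n_sessions = ns, n_trials = nt,
                   package_version = as.character(
                     utils::packageVersion("forgetfulRL")))
  attr(res, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res))
      utils::write.csv(res[[nm]],
                       file.path(out_dir, sprintf("%s_%s.csv", name, nm)),
                       row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, sprintf("%s_manifest.json", name)),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
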