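#' Run a simulation described by a flat configuration
#'
#' Reads a YAML (or JSON) configuration with sections
#' `agent {alpha, beta, gamma, phi, algorithm}`,
#' `env {kind, ...}` (`kind` one of `track`, `tmaze`, `elab_tmaze`;
#' remaining keys are passed to [linear_track()], [tmaze()] or
#' [elaborated_tmaze()]),
#' `run {n_trials, n_sessions, seed, step_cap}`, and optionally
#' `manipulation {onset_trial, factor}`, then runs the sessions and
#' summarizes them. When `out_dir` is given, writes a per-trial CSV
#' (`session`, `trial`, `steps`, `reward_total`), an optional per-step CSV
#' (`per_step_log: true` in the `run` section), and a JSON summary.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @param out_dir Optional output directory.
#' @return A list with `sessions` (list of `session_result`), `summary`
#'   (from [summarize_sessions()]), and for T-maze runs `metrics`
#'   (from [tmaze_metrics()]).
#' @export
simulate_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$env), !is.null(config$run))
  agent <- config$agent %||% list()
  params <- do.call(agent_params, agent[names(agent) %in%
    c("alpha", "beta", "gamma", "phi", "algorithm")])
  envc <- config$env
  kind <- envc$kind %||% "track"
  envc$kind <- NULL
  env <- switch(kind,
    track = do.call(linear_track, envc),
    tmaze = do.call(tmaze, envc),
    elab_tmaze = do.call(elaborated_tmaze, envc),
    stop("unknown env kind: ", kind)
  )
  run <- config$run
  n_trials <- as.integer(run$n_trials %||% 500L)
  n_sessions <- as.integer(run$n_sessions %||% 20L)
  seed <- as.integer(run$seed %||% 1L)
  step_cap <- run$step_cap %||% Inf
  per_step <- isTRUE(run$per_step_log)
  man <- if (!is.null(config$manipulation))
    da_manipulation(config$manipulation$factor %||% 1,
                    config$manipulation$onset_trial %||% 0) else NULL
  runner <- if (kind == "elab_tmaze") {
    function(sd) run_session_elab(env, params, n_trials, seed = sd,
                                  manipulation = man, step_cap = step_cap,
                                  record_steps = per_step)
  } else {
    function(sd) run_session(env, params, n_trials, seed = sd,
                             manipulation = man, step_cap = step_cap,
                             record_steps = per_step)
  }
  sessions <- lapply(session_seeds(seed, n_sessions), runner)
  summary <- summarize_sessions(sessions,
                                block = if (kind == "track") 5L else 10L)
  out <- list(sessions = sessions, summary = summary)
  if (kind != "track") out$metrics <- tmaze_metrics(sessions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    trials <- do.call(rbind, lapply(seq_along(sessions), function(i)
      data.frame(session = i, trial = sessions[[i]]$trials$trial,
                 steps = sessions[[i]]$trials$steps,
                 reward_total = sessions[[i]]$trials$reward)))
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    if (per_step) {
      logs <- do.call(rbind, lapply(seq_along(sessions), function(i)
        cbind(session = i, sessions[[i]]$steps)))
      utils::write.csv(logs, file.path(out_dir, "steps.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(blocks = summary$blocks, mean_steps = summary$mean_steps,
           se_steps = summary$se_steps,
           mean_delta_per_step = summary$mean_delta_per_step),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
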