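#' Agent parameters
#'
#' Bundles the learning parameters of the TD agent: the learning rate
#' `alpha`, the inverse temperature `beta` of softmax action selection, the
#' time discount factor `gamma`, the per-time-step decay rate `phi` of all
#' learned values, and the reward-prediction-error (RPE) algorithm.
#'
#' At every time step each learned value is multiplied by `1 - phi`, whether
#' or not the corresponding action was taken; `phi = 0` disables forgetting.
#'
#' @param alpha Learning rate, in `[0, 1]`. Default 0.5.
#' @param beta Inverse temperature of softmax selection, `>= 0`. `beta = 0`
#'   gives uniform choice; large `beta` approaches greedy choice. Default 5.
#' @param gamma Time discount factor, in `[0, 1]`. Default 1 (no discounting).
#' @param phi Decay (forgetting) rate per time step, in `[0, 1]`. Default 0.
#' @param algorithm `"q_learning"` (RPE uses the maximum candidate value at
#'   the new state) or `"sarsa"` (RPE uses the value of the action actually
#'   taken).
#'
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(phi = 0.01)
#' @export
agent_params <- function(alpha = 0.5, beta = 5, gamma = 1, phi = 0,
                         algorithm = c("q_learning", "sarsa")) {
  algorithm <- match.arg(algorithm)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
    is.numeric(phi), length(phi) == 1L, phi >= 0, phi <= 1
  )
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, phi = phi,
         algorithm = algorithm),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> alpha=%g beta=%g gamma=%g phi=%g algorithm=%s\n",
    x$alpha, x$beta, x$gamma, x$phi, x$algorithm))
  invisible(x)
}

#' Simulated dopamine blockade / depletion
#'
#' Describes a post-training manipulation that scales the RPE-dependent
#' increment of learned values: from trial `onset_trial + 1` onwards, the
#' update applied to the previous action's value becomes
#' `alpha * factor * delta` instead of `alpha * delta`. The logged RPE (the
#' simulated dopamine signal) is always the raw `delta`; only the value
#' update is scaled.
#'
#' @param factor Multiplier on the RPE inside the value update, in `[0, 1]`.
#'   0 models complete blockade, 0.25 partial blockade/depletion, 1 no
#'   manipulation.
#' @param onset_trial Number of completed trials after which the manipulation
#'   applies (the manipulation affects trials with index strictly greater
#'   than `onset_trial`).
#'
#' @return An object of class `da_manipulation`.
#' @examples
#' da_manipulation(factor = 0.25, onset_trial = 500)
#' @export
da_manipulation <- function(factor = 1, onset_trial = 0) {
  stopifnot(
    is.numeric(factor), length(factor) == 1L, factor >= 0, factor <= 1,
    is.numeric(onset_trial), length(onset_trial) == 1L, onset_trial >= 0
  )
  structure(
    list(factor = factor, onset_trial = as.integer(onset_trial)),
    class = "da_manipulation"
  )
}

#' @export
print.da_manipulation <- function(x, ...) {
  cat(sprintf("<da_manipulation> factor=%g after trial %d\n",
              x$factor, x$onset_trial))
  invisible(x)
}

# Effective update scaling for a given trial index.
manipulation_factor <- function(manipulation, trial_index) {
  if (is.null(manipulation)) return(1)
  if (trial_index > manipulation$onset_trial) manipulation$factor else 1
}
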