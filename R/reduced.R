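#' Parameters of the reduced two-variable model
#'
#' The reduced continuous-time model describes the values `q11` of `Stay`
#' and `q12` of `Go` at the state preceding the goal:
#' \deqn{dq11/dt = y \alpha (\gamma q12 - q11) - \psi q11}
#' \deqn{dq12/dt = \alpha (r - q12) - \psi q12}
#' where `y = exp(beta * (q11 - q12))` is the expected number of consecutive
#' `Stay` choices per trial. `psi` is the degree of value decay per trial;
#' it roughly corresponds to the per-step decay rate `phi` of the full model
#' multiplied by the trial length, but no automatic conversion is performed.
#' The analysis is restricted to the region `q11 <= q12`, where the max in
#' the `Stay` RPE resolves to `q12`.
#'
#' @param alpha Learning rate (default 0.5).
#' @param beta Inverse temperature (default 5).
#' @param gamma Time discount factor (default 1).
#' @param r Goal reward (default 1).
#' @param psi Decay degree per trial, `>= 0` (default 0).
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(alpha = 0.5, beta = 5, gamma = 1, r = 1,
                           psi = 0) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, gamma >= 0, gamma <= 1,
            r > 0, psi >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, r = r,
                 psi = psi),
            class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("<reduced_params> alpha=%g beta=%g gamma=%g r=%g psi=%g\n",
              x$alpha, x$beta, x$gamma, x$r, x$psi))
  invisible(x)
}

# Vectorized right-hand side; exponent clamped to keep exp() finite when
# Newton iterates wander outside the analysis region.
reduced_f <- function(q11, q12, p) {
  y <- exp(pmin(p$beta * (q11 - q12), 50))
  list(d11 = y * p$alpha * (p$gamma * q12 - q11) - p$psi * q11,
       d12 = p$alpha * (p$r - q12) - p$psi * q12)
}

#' Right-hand side of the reduced model
#'
#' @param state Numeric vector `c(q11, q12)` (`Stay`, `Go` values).
#' @param params A [reduced_params()] object.
#' @return Numeric vector `c(dq11, dq12)` of time derivatives.
#' @examples
#' reduced_rhs(c(1, 1), reduced_params())  # decay-free fixed point
#' @export
reduced_rhs <- function(state, params) {
  stopifnot(inherits(params, "reduced_params"), length(state) == 2L,
            is.numeric(state))
  f <- reduced_f(state[[1]], state[[2]], params)
  c(dq11 = f$d11, dq12 = f$d12)
}

# Stability from the sign pattern of Jacobian eigenvalue real parts,
# Jacobian by central differences.
classify_stability <- function(point, params, heps = 1e-7, tol = 1e-9) {
  jac <- pracma::jacobian(function(x) reduced_rhs(x, params), point,
                          heps = heps)
  re <- Re(eigen(jac, only.values = TRUE)$values)
  if (all(re < -tol)) return("stable")
  if (any(re > tol) && any(re < -tol)) return("saddle")
  if (all(re > tol)) return("unstable")
  "marginal"
}

#' Find the equilibria of the reduced model
#'
#' Multi-start damped Newton iteration from a `grid_n` x `grid_n` grid over
#' `[0, r]^2` intersected with the analysis region `q11 <= q12`. Converged
#' points are deduplicated within `dedupe` and classified by the eigenvalues
#' of a central-difference Jacobian (step 1e-7; real parts within `1e-9` of
#' zero are treated as marginal). Points that leave the region are
#' discarded.
#'
#' @param params A [reduced_params()] object.
#' @param grid_n Starts per axis (default 20).
#' @param tol Residual norm tolerance for convergence.
#' @param dedupe Merge distance for duplicate equilibria.
#' @return Data frame with one row per equilibrium: `q11`, `q12`, `p11`
#'   (softmax probability of `Stay` at the point), `stability`
#'   (`stable`/`saddle`/`unstable`/`marginal`), `psi`. Zero rows (with a
#'   warning) if no start converges.
#' @examples
#' find_equilibria(reduced_params(psi = 0.08))
#' @export
find_equilibria <- function(params, grid_n = 20L, tol = 1e-10,
                            dedupe = 1e-6) {
  stopifnot(inherits(params, "reduced_params"))
  g <- seq(0, params$r, length.out = grid_n)
  starts <- expand.grid(q11 = g, q12 = g)
  starts <- starts[starts$q11 <= starts$q12, ]
  q11 <- starts$q11; q12 <- starts$q12
  alpha <- params$alpha; beta <- params$beta
  gamma <- params$gamma; psi <- params$psi
  for (iter in 1:80) {
    y <- exp(pmin(beta * (q11 - q12), 50))
    f1 <- y * alpha * (gamma * q12 - q11) - psi * q11
    f2 <- alpha * (params$r - q12) - psi * q12
    # Jacobian is upper triangular in (q11, q12): dF2/dq11 = 0.
    j11 <- y * beta * alpha * (gamma * q12 - q11) - y * alpha - psi
    j12 <- -y * beta * alpha * (gamma * q12 - q11) + y * alpha * gamma
    j22 <- -alpha - psi
    d2 <- -f2 / j22
    d1 <- -(f1 + j12 * d2) / j11
    # damp: cap the step length to stay on the smooth part of exp()
    nrm <- sqrt(d1^2 + d2^2)
    shrink <- pmin(1, 0.25 * params$r / pmax(nrm, 1e-300))
    q11 <- q11 + shrink * d1
    q12 <- q12 + shrink * d2
  }
  res <- reduced_f(q11, q12, params)
  ok <- is.finite(q11) & is.finite(q12) &
    abs(res$d11) < tol & abs(res$d12) < tol &
    q11 <= q12 + 1e-8 & q11 > -1e-8
  if (!any(ok)) {
    warning("no equilibrium found from any start")
    return(data.frame(q11 = numeric(0), q12 = numeric(0),
                      p11 = numeric(0), stability = character(0),
                      psi = numeric(0)))
  }
  pts <- cbind(q11[ok], q12[ok])
  keep <- list()
  for (i in seq_len(nrow(pts))) {
    dup <- any(vapply(keep, function(p)
      sqrt(sum((p - pts[i, ])^2)) < dedupe, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- pts[i, ]
  }
  eq <- do.call(rbind, keep)
  eq <- eq[order(eq[, 1]), , drop = FALSE]
  data.frame(
    q11 = eq[, 1], q12 = eq[, 2],
    p11 = stats::plogis(beta * (eq[, 1] - eq[, 2])),
    stability = vapply(seq_len(nrow(eq)), function(i)
      classify_stability(eq[i, ], params), character(1)),
    psi = psi
  )
}

#' Bifurcation sweep over the decay degree
#'
#' Finds all equilibria (with stability and the `Stay` choice probability
#' `p11`) for each value of `psi` in `psi_grid`. With `refine = TRUE`, grid
#' intervals where the equilibrium count changes are subdivided once to
#' localize the branch folds.
#'
#' @param params A [reduced_params()] object (`psi` is overridden by the
#'   grid).
#' @param psi_grid Monotone increasing grid of decay degrees.
#' @param refine Subdivide intervals where the branch count changes.
#' @param grid_n Starts per axis passed to [find_equilibria()].
#' @return Data frame stacking [find_equilibria()] output over the grid.
#' @examples
#' bd <- bifurcation_sweep(reduced_params(), seq(0, 0.12, by = 0.005))
#' table(bd$stability)
#' @export
bifurcation_sweep <- function(params, psi_grid = seq(0, 0.12, by = 2e-4),
                              refine = TRUE, grid_n = 20L) {
  stopifnot(inherits(params, "reduced_params"), !is.unsorted(psi_grid))
  one <- function(psi) {
    p <- params; p$psi <- psi
    suppressWarnings(find_equilibria(p, grid_n = grid_n))
  }
  out <- lapply(psi_grid, one)
  if (refine && length(psi_grid) > 1L) {
    counts <- vapply(out, nrow, integer(1))
    flips <- which(diff(counts) != 0L)
    extra <- unlist(lapply(flips, function(i)
      seq(psi_grid[i], psi_grid[i + 1L], length.out = 12L)[2:11]))
    if (length(extra)) out <- c(out, lapply(extra, one))
  }
  out <- do.call(rbind, out)
  out[order(out$psi, out$q11), ]
}

#' Locate the upper saddle-node bifurcation
#'
#' Bisects on the decay degree `psi` for the point where the number of
#' equilibria of the reduced model drops from 3 (bistable regime) to 1
#' (unique stable equilibrium with a large Go/Stay contrast). With the
#' standard parameters (`alpha = 0.5`, `beta = 5`, `gamma = 1`, `r = 1`)
#' this critical degree is approximately 0.0559.
#'
#' @param params A [reduced_params()] object.
#' @param bracket Length-2 vector of `psi` values bracketing the 3 -> 1
#'   transition.
#' @param tol Bisection tolerance (default `1e-5`).
#' @param grid_n Starts per axis for [find_equilibria()].
#' @return The critical decay degree `psi*`.
#' @examples
#' \donttest{
#' find_saddle_node_upper(reduced_params())
#' }
#' @export
find_saddle_node_upper <- function(params, bracket = c(0.05, 0.09),
                                   tol = 1e-5, grid_n = 20L) {
  stopifnot(inherits(params, "reduced_params"), length(bracket) == 2L,
            bracket[1] < bracket[2])
  count <- function(psi) {
    p <- params; p$psi <- psi
    nrow(suppressWarnings(find_equilibria(p, grid_n = grid_n)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (count(lo) < 3L)
    stop("lower bracket end is not in the bistable (3-equilibria) regime")
  if (count(hi) != 1L)
    stop("upper bracket end does not have a unique equilibrium")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) >= 3L) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Nullcline field of the reduced model
#'
#' Evaluates the two time derivatives on a square grid over
#' `[0, 1.05 r]^2`, for drawing the nullclines (e.g. with
#' `contour(..., levels = 0)`). Points outside the analysis region
#' `q11 <= q12` are reported too; mask them if the region convention is
#' wanted.
#'
#' @param params A [reduced_params()] object.
#' @param n Grid points per axis.
#' @return Data frame `q11`, `q12`, `dq11`, `dq12`, `in_region`.
#' @export
reduced_nullclines <- function(params, n = 201L) {
  stopifnot(inherits(params, "reduced_params"))
  g <- seq(0, 1.05 * params$r, length.out = n)
  gr <- expand.grid(q11 = g, q12 = g)
  f <- reduced_f(gr$q11, gr$q12, params)
  data.frame(gr, dq11 = f$d11, dq12 = f$d12,
             in_region = gr$q11 <= gr$q12)
}
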