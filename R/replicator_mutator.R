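#' Uniform mutation matrix
#'
#' Row-stochastic mutation matrix in which every type mutates to each of the
#' other `n - 1` types with equal probability `q / (n - 1)` and stays put
#' with probability `1 - q`. At `q = 0` mutation is absent (replicator
#' dynamics); at the maximal value `q = (n - 1) / n` a type is equally
#' likely to become any type, including itself.
#'
#' @param n Number of types (actions).
#' @param q Mutation strength, `0 <= q <= (n - 1) / n`.
#' @return An `n x n` numeric matrix whose rows sum to 1.
#' @examples
#' build_mutation_matrix(3, 0)    # identity
#' build_mutation_matrix(4, 3/4)  # all entries 1/4
#' @export
build_mutation_matrix <- function(n, q) {
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2")
  if (q < 0 || q > (n - 1) / n)
    stop(sprintf("mutation strength q must lie in [0, %g]", (n - 1) / n))
  Q <- matrix(q / (n - 1), n, n)
  diag(Q) <- 1 - q
  Q
}

#' Fitness of each claim against the current population
#'
#' Expected payoff of each action against an opponent drawn from the
#' population: `f_i = sum_j P[i, j] x_j`.
#'
#' @param x Frequency vector on the simplex.
#' @param P Payoff matrix with side `length(x)`.
#' @return Numeric vector of fitnesses.
#' @export
fitness_vector <- function(x, P) {
  if (length(x) != ncol(P)) stop("length(x) must match the payoff matrix side")
  as.vector(P %*% x)
}

#' Right-hand side of the replicator-mutator equation
#'
#' `dx_i/dt = sum_j x_j f_j q_{ji} - x_i phi`, where `phi = sum_i x_i f_i`
#' is the average population fitness. With the identity mutation matrix this
#' reduces to the replicator equation `dx_i/dt = x_i (f_i - phi)`.
#'
#' @param x Frequency vector on the simplex.
#' @param P Payoff matrix.
#' @param Q Row-stochastic mutation matrix.
#' @return Numeric vector of time derivatives (sums to zero).
#' @export
rm_rhs <- function(x, P, Q) {
  w <- x * fitness_vector(x, P)
  phi <- sum(w)
  as.vector(crossprod(Q, w)) - x * phi
}

# rhs specialised to the uniform mutation kernel of build_mutation_matrix():
# crossprod(Q, w) = (1 - q) w + q/(n-1) (phi - w); avoids the n x n product.
rm_rhs_uniform <- function(x, P, q) {
  w <- x * as.vector(P %*% x)
  phi <- sum(w)
  n <- length(x)
  if (q == 0) w - x * phi
  else (1 - q) * w + (q / (n - 1)) * (phi - w) - x * phi
}

#' Integrate the replicator-mutator dynamics to equilibrium
#'
#' Integrates the replicator-mutator equation for a Traveler's Dilemma
#' claim population until the dynamics stalls (`max |dx/dt| < tol`) or the
#' horizon `t_max` is reached. Integration uses the adaptive, stiffness-
#' switching `lsodar` solver with root-finding on the equilibrium
#' criterion, so the run stops as soon as the state is stationary.
#'
#' @param game A [td_game()] object.
#' @param q Mutation strength, `0 <= q <= (n - 1) / n`.
#' @param x0 Initial frequencies; default uniform `1/n`. Must be a
#'   nonnegative vector summing to 1 (within `1e-8`).
#' @param t_max Integration horizon in time units.
#' @param tol Equilibrium tolerance on `max |dx/dt|`.
#' @param times Optional sampling times for the stored trajectory; defaults
#'   to 201 points spanning `[0, t_max]` log-spaced after 0 so both fast
#'   early sorting and slow late drift are visible.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return An object of class `"rm_equilibrium"`: list with `x` (final
#'   frequencies, renormalized onto the simplex), `converged`, `t_end`,
#'   `trajectory` (matrix, first column `time`, then one column per claim),
#'   `game`, `q`, and the equilibrium summary fields `c_high_freq`,
#'   `c_avg`, `avg_payoff`.
#' @examples
#' g <- td_game(2, 10, 2)
#' eq <- replicator_mutator(g, q = 0)   # pure replicator: Nash claim wins
#' eq$c_high_freq                       # 2
#' @export
replicator_mutator <- function(game, q, x0 = NULL,
                               t_max = 1e5, tol = 1e-10,
                               times = NULL, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(game, "td_game"))
  n <- game$n_actions
  if (q < 0 || q > (n - 1) / n)
    stop(sprintf("mutation strength q must lie in [0, %g]", (n - 1) / n))
  if (is.null(x0)) x0 <- rep(1 / n, n)
  if (length(x0) != n) stop("x0 must have one entry per claim")
  if (any(x0 < 0) || abs(sum(x0) - 1) > 1e-8)
    stop("x0 must be a nonnegative vector summing to 1")

  if (is.null(times)) {
    # log-spaced after t = 1 so early elimination and late drift both resolve
    times <- unique(c(0, exp(seq(log(1e-2), log(t_max), length.out = 200))))
  } else {
    times <- sort(unique(c(0, times)))
  }

  P <- payoff_matrix(game)
  deriv <- function(t, x, parms) list(rm_rhs_uniform(x, P, q))
  rootfun <- function(t, x, parms) max(abs(rm_rhs_uniform(x, P, q))) - tol

  # maxsteps caps the cost of cells whose final relaxation is pathologically
  # slow (near phase boundaries); the state returned at the cap is ranked
  # like the equilibrium for all summary purposes
  out <- suppressWarnings(
    deSolve::lsodar(y = x0, times = times, func = deriv,
                    rootfunc = rootfun, rtol = rtol, atol = atol,
                    maxsteps = 20000))
  t_end <- out[nrow(out), 1]
  x <- out[nrow(out), -1]
  converged <- !is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0
  # project back onto the simplex (integrator drift is < 1e-8)
  x <- pmax(x, 0)
  x <- x / sum(x)

  traj <- out
  colnames(traj) <- c("time", game$claims)
  s <- summarize_equilibrium(x, P, game)
  structure(
    list(x = stats::setNames(as.numeric(x), game$claims),
         converged = converged, t_end = t_end,
         trajectory = traj, game = game, q = q, tol = tol,
         c_high_freq = s$c_high_freq, c_avg = s$c_avg,
         avg_payoff = s$avg_payoff),
    class = "rm_equilibrium"
  )
}

#' Summary statistics of a claim-frequency state
#'
#' @param x Frequency vector on the simplex (one entry per claim).
#' @param P Payoff matrix (defaults to the game's).
#' @param game A [td_game()] object.
#' @return List with `c_high_freq` (claim with maximal frequency, ties
#'   broken toward the lowest claim), `c_avg` (frequency-weighted mean
#'   claim) and `avg_payoff` (`phi = sum_i x_i f_i`).
#' @export
summarize_equilibrium <- function(x, P = payoff_matrix(game), game) {
  stopifnot(inherits(game, "td_game"))
  if (length(x) != game$n_actions) stop("x must have one entry per claim")
  f <- fitness_vector(x, P)
  list(c_high_freq = game$claims[which.max(x)], # which.max: first = lowest claim
       c_avg = sum(x * game$claims),
       avg_payoff = sum(x * f))
}

#' @export
print.rm_equilibrium <- function(x, ...) {
  cat("Replicator-mutator equilibrium\n")
  cat(sprintf("  game: [%d, %d], R = %g;  q = %g\n",
              x$game$L, x$game$U, x$game$R, x$q))
  cat(sprintf("  %s at t = %.4g\n",
              if (x$converged) "converged (max |dx/dt| < tol)"
              else "NOT converged by t_max", x$t_end))
  cat(sprintf("  c_highFreq = %d,  c_avg = %.3f,  avg payoff = %.3f\n",
              x$c_high_freq, x$c_avg, x$avg_payoff))
  invisible(x)
}

#' @export
summary.rm_equilibrium <- function(object, ...) {
  print(object)
  top <- sort(object$x, decreasing = TRUE)[1:min(5, length(object$x))]
  cat("  top claim frequencies:\n")
  for (nm in names(top))
    cat(sprintf("    claim %s: %.4f\n", nm, top[[nm]]))
  invisible(object)
}

#' @export
plot.rm_equilibrium <- function(x, ...) {
  traj <- x$trajectory
  tt <- traj[, 1]
  graphics::matplot(tt, traj[, -1], type = "l", lty = 1,
                    xlab = "time", ylab = "frequency",
                    main = sprintf("replicator-mutator, q = %g, R = %g",
                                   x$q, x$game$R), ...)
  invisible(x)
}
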