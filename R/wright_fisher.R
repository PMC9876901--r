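#' Accumulated payoff of every individual in a population
#'
#' Each individual plays the Traveler's Dilemma once against every other
#' member of the population (self-interactions excluded) and the payoffs are
#' summed. Computation aggregates over claim counts, so the cost is
#' `O(A^2 + N)` in the action count `A` rather than `O(N^2)`.
#'
#' @param pop Integer vector of claims (the population).
#' @param game A [td_game()] object.
#' @param P Payoff matrix, defaults to `payoff_matrix(game)`.
#' @param mode `"sum"` (accumulated payoff over the `N - 1` opponents) or
#'   `"mean"` (per-opponent average; rescales the effective selection
#'   intensity).
#' @return Numeric vector, one accumulated payoff per individual.
#' @export
accumulated_payoff <- function(pop, game, P = payoff_matrix(game),
                               mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  check_claims(pop, game, "population claims")
  idx <- claim_to_index(pop, game)
  counts <- tabulate(idx, nbins = game$n_actions)
  # payoff of claim c against the whole population, minus the self-pairing
  per_claim <- as.vector(P %*% counts) - unname(diag(P))
  out <- per_claim[idx]
  if (mode == "mean") out <- out / (length(pop) - 1)
  unname(out)
}

#' Fitness-proportional sampling weights
#'
#' Maps accumulated payoffs to Wright-Fisher sampling weights via the
#' exponential fitness function `f = exp(rho * Pi)`. The maximum payoff is
#' subtracted before exponentiation; the weights are normalization-invariant
#' under such shifts, so this avoids overflow without changing the process.
#'
#' @param Pi Numeric vector of accumulated payoffs.
#' @param rho Selection intensity, `rho >= 0`.
#' @return Normalized weights summing to 1.
#' @examples
#' fitness_weights(c(0, log(2)), rho = 1) # c(1/3, 2/3)
#' @export
fitness_weights <- function(Pi, rho) {
  if (rho < 0) stop("selection intensity rho must be >= 0")
  w <- exp(rho * (Pi - max(Pi)))
  w / sum(w)
}

#' Mutate claims by a bounded step
#'
#' A mutating claim moves by a step drawn uniformly from `{1, ..., delta}`
#' (or exactly `delta` when `step_dist = "fixed"`), with sign up or down
#' with probability 1/2 each; results outside `[L, U]` are replaced by the
#' nearest bound.
#'
#' @param claims Integer vector of claims to mutate.
#' @param delta Maximal mutation size (claim units), integer `>= 1`.
#' @param game A [td_game()] object.
#' @param step_dist `"uniform"` (step size uniform on `1:delta`) or
#'   `"fixed"` (step size always `delta`).
#' @return Integer vector of mutated claims, clamped to `[L, U]`.
#' @export
mutate_claims <- function(claims, delta, game,
                          step_dist = c("uniform", "fixed")) {
  step_dist <- match.arg(step_dist)
  if (delta < 1 || delta != round(delta))
    stop("delta must be an integer >= 1")
  k <- length(claims)
  if (k == 0) return(integer(0))
  size <- if (step_dist == "fixed") rep(as.integer(delta), k)
          else sample.int(as.integer(delta), k, replace = TRUE)
  sign <- ifelse(stats::runif(k) < 0.5, -1L, 1L)
  pmin(pmax(claims + sign * size, game$L), game$U)
}

#' One Wright-Fisher generation
#'
#' Samples `N` offspring claims with replacement, weighted by
#' `exp(rho * Pi)`, then mutates each offspring independently with
#' probability `mu`.
#'
#' @param pop Integer vector of claims (current generation).
#' @param game A [td_game()] object.
#' @param mu Mutation probability per individual per generation.
#' @param delta Maximal mutation size.
#' @param rho Selection intensity.
#' @param P Payoff matrix, defaults to `payoff_matrix(game)`.
#' @param step_dist,payoff_mode Passed to [mutate_claims()] and
#'   [accumulated_payoff()].
#' @return Integer vector of claims (next generation).
#' @export
wf_step <- function(pop, game, mu, delta, rho, P = payoff_matrix(game),
                    step_dist = "uniform", payoff_mode = "sum") {
  N <- length(pop)
  idx <- claim_to_index(pop, game)
  counts <- tabulate(idx, nbins = game$n_actions)
  per_claim <- as.vector(P %*% counts) - diag(P)
  if (payoff_mode == "mean") per_claim <- per_claim / (N - 1)
  # individuals sharing a claim share a weight: sample at the claim level
  present <- counts > 0
  w <- numeric(game$n_actions)
  w[present] <- counts[present] *
    exp(rho * (per_claim[present] - max(per_claim[present])))
  offspring <- sample(game$claims, N, replace = TRUE, prob = w)
  mut <- stats::runif(N) < mu
  if (any(mut))
    offspring[mut] <- mutate_claims(offspring[mut], delta, game, step_dist)
  offspring
}

#' Run the Wright-Fisher process
#'
#' Simulates `t` non-overlapping generations of a population of `N`
#' Traveler's Dilemma players. Each generation is resampled with
#' replacement, with weights `exp(rho * Pi)` where `Pi` is the accumulated
#' payoff against all other individuals; each offspring then mutates with
#' probability `mu` by a bounded step of at most `delta` claim units.
#'
#' @param game A [td_game()] object.
#' @param N Population size, `>= 2`.
#' @param mu Mutation probability per individual per generation, in `[0, 1]`.
#' @param delta Maximal mutation size, integer `>= 1`.
#' @param rho Selection intensity, `>= 0`.
#' @param t Number of generations, `>= 1`.
#' @param seed Optional RNG seed for reproducibility.
#' @param init Optional initial population (integer claims, length `N`);
#'   default: each claim drawn uniformly from the action space.
#' @param step_dist Mutation step law, see [mutate_claims()].
#' @param payoff_mode `"sum"` or `"mean"`, see [accumulated_payoff()].
#' @param summary_window Number of trailing generations averaged into
#'   `c_avg_final` (default 100, capped at `t`); averaging suppresses drift
#'   noise in the converged regime.
#' @return An object of class `"wf_run"`: list with `series` (average claim
#'   per generation, length `t + 1` including the initial state), `final`
#'   (claims of the last generation), `c_avg_final`, and the call
#'   parameters.
#' @examples
#' g <- td_game(2, 100, 2)
#' run <- wright_fisher(g, N = 50, mu = 0.1, delta = 10, rho = 0.1,
#'                      t = 100, seed = 1)
#' run$c_avg_final
#' @export
wright_fisher <- function(game, N = 100, mu, delta, rho, t = 1000,
                          seed = NULL, init = NULL,
                          step_dist = c("uniform", "fixed"),
                          payoff_mode = c("sum", "mean"),
                          summary_window = 100) {
  stopifnot(inherits(game, "td_game"))
  step_dist <- match.arg(step_dist)
  payoff_mode <- match.arg(payoff_mode)
  if (N < 2 || N != round(N)) stop("population size N must be an integer >= 2")
  if (mu < 0 || mu > 1) stop("mutation probability mu must lie in [0, 1]")
  if (delta < 1 || delta != round(delta)) stop("delta must be an integer >= 1")
  if (rho < 0) stop("selection intensity rho must be >= 0")
  if (t < 1 || t != round(t)) stop("t must be an integer >= 1")
  if (!is.null(seed)) set.seed(seed)

  P <- payoff_matrix(game)
  if (is.null(init)) {
    pop <- sample(game$claims, N, replace = TRUE)
  } else {
    if (length(init) != N) stop("init must have length N")
    pop <- check_claims(init, game, "init")
  }
  series <- numeric(t + 1)
  series[1] <- mean(pop)
  for (gen in seq_len(t)) {
    pop <- wf_step(pop, game, mu, delta, rho, P, step_dist, payoff_mode)
    series[gen + 1] <- mean(pop)
  }
  win <- min(summary_window, t)
  structure(
    list(series = series, final = pop,
         c_avg_final = mean(series[(t + 2 - win):(t + 1)]),
         game = game, N = N, mu = mu, delta = delta, rho = rho, t = t,
         seed = seed, step_dist = step_dist, payoff_mode = payoff_mode),
    class = "wf_run"
  )
}

#' @export
print.wf_run <- function(x, ...) {
  cat("Wright-Fisher run\n")
  cat(sprintf("  game: [%d, %d], R = %g;  N = %d, mu = %g, delta = %d, rho = %g, t = %d\n",
              x$game$L, x$game$U, x$game$R, x$N, x$mu, x$delta, x$rho, x$t))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  cat(sprintf("  final average claim (trailing mean): %.3f\n", x$c_avg_final))
  invisible(x)
}

#' @export
plot.wf_run <- function(x, ...) {
  graphics::plot(seq_along(x$series) - 1, x$series, type = "l",
                 xlab = "generation", ylab = "average claim",
                 ylim = range(x$game$claims),
                 main = sprintf("Wright-Fisher: mu = %g, delta = %d, rho = %g",
                                x$mu, x$delta, x$rho), ...)
  invisible(x)
}
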