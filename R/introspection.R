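#' Fermi acceptance probability
#'
#' Probability that a player adopts an alternative action yielding payoff
#' `pi_alt` when the current action yields `pi_cur`:
#' `p = 1 / (1 + exp(-beta * (pi_alt - pi_cur)))`. At `beta = 0` every
#' alternative is accepted with probability 1/2; as `beta` grows the choice
#' becomes a sharp payoff comparison, with ties still resolved at 1/2.
#'
#' @param pi_alt Payoff of the alternative action.
#' @param pi_cur Payoff of the current action.
#' @param beta Selection intensity, `beta >= 0`.
#' @return Acceptance probability in `[0, 1]`; vectorized.
#' @examples
#' fermi_probability(1, 1, 10)       # 0.5
#' fermi_probability(log(3), 0, 1)   # 0.75
#' @export
fermi_probability <- function(pi_alt, pi_cur, beta) {
  if (any(beta < 0)) stop("selection intensity beta must be >= 0")
  stats::plogis(beta * (pi_alt - pi_cur))
}

# unordered-pair index for claims i <= j (1-based action indices)
pair_index <- function(i, j, A) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * A - (lo - 1) * lo / 2 + hi
}

#' Transition matrix of the two-player introspection chain
#'
#' State space: ordered claim pairs `(n1, n2)`, `A^2` states for `A`
#' actions. In one step a player is chosen uniformly (probability 1/2
#' each), an alternative claim is proposed uniformly over all `A` claims
#' (self-proposals included; they are no-ops accepted at probability 1/2),
#' and the chosen player switches with the Fermi probability evaluated
#' against the opponent's fixed claim. All remaining probability stays on
#' the self-loop.
#'
#' @param game A [td_game()] object.
#' @param beta Selection intensity, `beta >= 0`.
#' @return An object of class `"introspection_chain"`: list with the sparse
#'   row-stochastic `transition` matrix (`dgCMatrix`, `A^2 x A^2`), `states`
#'   (data.frame with claims `n1`, `n2`; state `k` has `n1` varying
#'   fastest), `game` and `beta`.
#' @examples
#' chain <- build_transition_matrix(td_game(2, 6, 2), beta = 1)
#' nrow(chain$states) # 25
#' @export
build_transition_matrix <- function(game, beta) {
  stopifnot(inherits(game, "td_game"))
  if (beta < 0) stop("selection intensity beta must be >= 0")
  A <- game$n_actions
  P <- payoff_matrix(game)
  ii <- rep(seq_len(A), times = A)   # player 1 claim index, varies fastest
  jj <- rep(seq_len(A), each = A)    # player 2 claim index
  ns <- A * A
  sid <- seq_len(ns)
  ti <- integer(2 * A * ns); tj <- integer(2 * A * ns); tx <- numeric(2 * A * ns)
  pos <- 0L
  cur1 <- P[cbind(ii, jj)]           # payoff of player 1 in each state
  cur2 <- P[cbind(jj, ii)]           # payoff of player 2
  for (a in seq_len(A)) {
    p1 <- fermi_probability(P[a, jj], cur1, beta) / (2 * A) # 1 switches to a
    p2 <- fermi_probability(P[a, ii], cur2, beta) / (2 * A) # 2 switches to a
    idx <- pos + seq_len(2 * ns)
    ti[idx] <- c(sid, sid)
    tj[idx] <- c((jj - 1) * A + a, (a - 1) * A + ii)
    tx[idx] <- c(p1, p2)
    pos <- pos + 2L * ns
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ns, ns))
  rs <- Matrix::rowSums(M)
  Matrix::diag(M) <- Matrix::diag(M) + (1 - rs)
  structure(
    list(transition = M,
         states = data.frame(n1 = game$claims[ii], n2 = game$claims[jj]),
         game = game, beta = beta),
    class = "introspection_chain"
  )
}

#' @export
print.introspection_chain <- function(x, ...) {
  cat("Introspection-dynamics Markov chain\n")
  cat(sprintf("  game: [%d, %d], R = %g;  beta = %g\n",
              x$game$L, x$game$U, x$game$R, x$beta))
  cat(sprintf("  %d states (ordered claim pairs), %d nonzero transitions\n",
              nrow(x$states), Matrix::nnzero(x$transition)))
  invisible(x)
}

# Build the chain lumped by player exchange onto unordered claim pairs
# {i, j}. The ordered chain is lumpable because the update rule is
# player-symmetric; the lumped chain has A(A+1)/2 states, small enough for
# an exact dense linear solve even when the full chain is not.
build_lumped_chain <- function(game, beta) {
  A <- game$n_actions
  P <- payoff_matrix(game)
  np <- A * (A + 1) / 2
  lo <- unlist(lapply(seq_len(A), function(i) rep(i, A - i + 1)))
  hi <- unlist(lapply(seq_len(A), function(i) i:A))
  sid <- seq_len(np)
  ti <- integer(2 * A * np); tj <- integer(2 * A * np); tx <- numeric(2 * A * np)
  pos <- 0L
  cur_lo <- P[cbind(lo, hi)]  # payoff of the lo-claim player
  cur_hi <- P[cbind(hi, lo)]  # payoff of the hi-claim player
  for (a in seq_len(A)) {
    p1 <- fermi_probability(P[a, hi], cur_lo, beta) / (2 * A)
    p2 <- fermi_probability(P[a, lo], cur_hi, beta) / (2 * A)
    idx <- pos + seq_len(2 * np)
    ti[idx] <- c(sid, sid)
    tj[idx] <- c(pair_index(rep(a, np), hi, A), pair_index(lo, rep(a, np), A))
    tx[idx] <- c(p1, p2)
    pos <- pos + 2L * np
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(np, np))
  rs <- Matrix::rowSums(M)
  Matrix::diag(M) <- Matrix::diag(M) + (1 - rs)
  list(M = M, lo = lo, hi = hi)
}

#' Exact stationary distribution of the introspection chain
#'
#' Solves `v' P = v'` with `sum(v) = 1`. The default method exploits the
#' chain's player-exchange symmetry: the chain is lumped exactly onto
#' unordered claim pairs (`A(A+1)/2` states), one balance equation is
#' replaced by the normalization constraint, and the resulting dense system
#' is solved by LAPACK; the solution is then unfolded symmetrically onto
#' ordered pairs. `method = "power"` iterates `v <- P' v` instead and is
#' kept as an independent cross-check (slow near phase boundaries). The
#' residual `max |v'P - v|` is always evaluated on the full ordered-pair
#' chain.
#'
#' @param chain An [build_transition_matrix()] object.
#' @param method `"lumped"` (exact dense solve, default) or `"power"`.
#' @param tol Residual tolerance; the solve fails (error) if the achieved
#'   residual exceeds it. Also the stopping tolerance for `"power"`.
#' @param max_iter Iteration cap for `"power"`.
#' @return An object of class `"stationary_dist"`: list with `v`
#'   (probability over ordered states, same order as `chain$states`),
#'   `marginal` (per-claim probability for one player), `c_avg`,
#'   `avg_payoff`, `residual`, `method`, `game`, `beta`.
#' @examples
#' chain <- build_transition_matrix(td_game(2, 6, 2), beta = 0)
#' sd <- stationary_distribution(chain)
#' sd$c_avg # 4: uniform over claims 2..6
#' @export
stationary_distribution <- function(chain, method = c("lumped", "power"),
                                    tol = 1e-10, max_iter = 500000) {
  stopifnot(inherits(chain, "introspection_chain"))
  method <- match.arg(method)
  game <- chain$game
  A <- game$n_actions
  if (method == "lumped") {
    lum <- build_lumped_chain(game, chain$beta)
    np <- nrow(lum$M)
    B <- as.matrix(Matrix::t(lum$M)) - diag(np)
    B[np, ] <- 1
    w <- solve(B, c(rep(0, np - 1), 1))
    v <- numeric(A * A)
    diag_pair <- lum$lo == lum$hi
    k1 <- (lum$hi - 1) * A + lum$lo
    k2 <- (lum$lo - 1) * A + lum$hi
    v[k1[diag_pair]] <- w[diag_pair]
    v[k1[!diag_pair]] <- w[!diag_pair] / 2
    v[k2[!diag_pair]] <- w[!diag_pair] / 2
  } else {
    Mt <- Matrix::t(chain$transition)
    v <- rep(1 / (A * A), A * A)
    for (it in seq_len(max_iter)) {
      vn <- as.vector(Mt %*% v)
      if (max(abs(vn - v)) < tol / 2) { v <- vn; break }
      v <- vn
    }
  }
  v <- pmax(v, 0)
  v <- v / sum(v)
  residual <- max(abs(as.vector(Matrix::t(chain$transition) %*% v) - v))
  if (residual > tol)
    stop(sprintf("stationary solve failed: residual %.3e exceeds tol %.3e",
                 residual, tol))
  s <- summarize_stationary(v, game)
  structure(
    list(v = v, marginal = s$marginal, c_avg = s$c_avg,
         avg_payoff = s$avg_payoff, residual = residual, method = method,
         game = game, beta = chain$beta),
    class = "stationary_dist"
  )
}

#' Summaries of a stationary distribution over claim pairs
#'
#' @param v Probability vector over ordered claim pairs (player-1 claim
#'   varying fastest), or a `"stationary_dist"` object.
#' @param game A [td_game()] object (ignored when `v` carries one).
#' @param P Payoff matrix, defaults to the game's.
#' @return List with `c_avg` (mean of the two players' claims), `avg_payoff`
#'   (mean of the two players' payoffs) and `marginal` (per-claim
#'   probability for one player; by symmetry the same for both).
#' @export
summarize_stationary <- function(v, game, P = payoff_matrix(game)) {
  if (inherits(v, "stationary_dist")) { game <- v$game; P <- payoff_matrix(game); v <- v$v }
  stopifnot(inherits(game, "td_game"))
  A <- game$n_actions
  if (length(v) != A * A) stop("v must have A^2 entries")
  V <- matrix(v, A, A)  # rows: player-1 claim, cols: player-2 claim
  cl <- game$claims
  marginal <- (rowSums(V) + colSums(V)) / 2
  list(c_avg = sum(marginal * cl),
       avg_payoff = sum(V * (P + t(P)) / 2),
       marginal = marginal)
}

#' @export
print.stationary_dist <- function(x, ...) {
  cat("Stationary distribution of introspection dynamics\n")
  cat(sprintf("  game: [%d, %d], R = %g;  beta = %g\n",
              x$game$L, x$game$U, x$game$R, x$beta))
  cat(sprintf("  method: %s, residual %.2e\n", x$method, x$residual))
  cat(sprintf("  c_avg = %.3f, avg payoff = %.3f, modal claim = %d\n",
              x$c_avg, x$avg_payoff, x$game$claims[which.max(x$marginal)]))
  invisible(x)
}

#' @export
plot.stationary_dist <- function(x, ...) {
  graphics::plot(x$game$claims, x$marginal, type = "h",
                 xlab = "claim", ylab = "stationary probability",
                 main = sprintf("beta = %g, R = %g", x$beta, x$game$R), ...)
  invisible(x)
}

#' Simulate an introspection-dynamics trajectory
#'
#' Seeded simulation of the two-player introspection chain: per step one
#' player, chosen uniformly, compares a uniformly proposed alternative
#' claim with their current claim against the opponent's fixed claim and
#' switches with the Fermi probability. The step loop is compiled; it draws
#' from R's RNG so results are reproducible via `seed`.
#'
#' @param game A [td_game()] object.
#' @param beta Selection intensity, `beta >= 0`.
#' @param steps Number of chain steps.
#' @param seed Optional RNG seed.
#' @param init Length-2 integer vector of initial claims; default: both
#'   drawn uniformly from the action space.
#' @return An object of class `"introspection_sim"`: list with `claims`
#'   (integer matrix, `steps + 1` rows, columns `n1`, `n2`), `game`,
#'   `beta`, `seed`.
#' @examples
#' sim <- simulate_trajectory(td_game(2, 100, 2), beta = 1,
#'                            steps = 1000, seed = 7)
#' colMeans(sim$claims)
#' @export
simulate_trajectory <- function(game, beta, steps, seed = NULL, init = NULL) {
  stopifnot(inherits(game, "td_game"))
  if (beta < 0) stop("selection intensity beta must be >= 0")
  if (steps < 1 || steps != round(steps)) stop("steps must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- sample(game$claims, 2, replace = TRUE)
  init <- check_claims(init, game, "init")
  if (length(init) != 2) stop("init must hold two claims")
  claims <- simulate_introspection_cpp(game$L, game$U, game$R, beta,
                                       as.integer(steps), init[1], init[2])
  colnames(claims) <- c("n1", "n2")
  structure(list(claims = claims, game = game, beta = beta, seed = seed),
            class = "introspection_sim")
}

#' @export
print.introspection_sim <- function(x, ...) {
  n <- nrow(x$claims) - 1
  cat("Introspection-dynamics trajectory\n")
  cat(sprintf("  game: [%d, %d], R = %g;  beta = %g;  %d steps\n",
              x$game$L, x$game$U, x$game$R, x$beta, n))
  cat(sprintf("  time-average claim: %.2f\n", mean(x$claims)))
  invisible(x)
}

#' @export
plot.introspection_sim <- function(x, thin = max(1, nrow(x$claims) %/% 5000), ...) {
  idx <- seq(1, nrow(x$claims), by = thin)
  graphics::matplot(idx - 1, x$claims[idx, ], type = "s", lty = 1,
                    xlab = "step", ylab = "claim",
                    ylim = range(x$game$claims),
                    main = sprintf("introspection, beta = %g, R = %g",
                                   x$beta, x$game$R), ...)
  invisible(x)
}
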