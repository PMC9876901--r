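# Independent oracles used across the test files. These re-derive expected
# behaviour from first principles (enumeration, brute force, small-step
# integration) without calling the code paths they check.

# Brute-force classification of the 2x2 restriction of the game to claims
# {n, n + s}: enumerate dominance and pure Nash equilibria directly from
# the payoff rule.
oracle_classify <- function(n, s, game) {
  a <- n; b <- n + s
  paa <- payoff(a, a, game); pab <- payoff(a, b, game)
  pba <- payoff(b, a, game); pbb <- payoff(b, b, game)
  dom_a <- paa > pba && pab > pbb
  dom_b <- pba > paa && pbb > pab
  nash_aa <- paa >= pba
  nash_bb <- pbb >= pab
  if ((dom_a && pbb > paa) || (dom_b && paa > pbb)) "prisoners_dilemma"
  else if (nash_aa && nash_bb && !dom_a && !dom_b) "coordination"
  else "other"
}

# Risk dominance by the Nash-product of deviation losses for a general
# two-player game (row payoffs A, column payoffs B): (b,b) risk-dominates
# (a,a) iff the product of losses from unilateral deviation out of (b,b)
# exceeds that of (a,a).
oracle_risk_dominant <- function(n, s, game) {
  a <- n; b <- n + s
  A <- matrix(c(payoff(a, a, game), payoff(a, b, game),
                payoff(b, a, game), payoff(b, b, game)), 2, 2, byrow = TRUE)
  B <- t(A) # symmetric game
  prod_aa <- (A[1, 1] - A[2, 1]) * (B[1, 1] - B[1, 2])
  prod_bb <- (A[2, 2] - A[1, 2]) * (B[2, 2] - B[2, 1])
  if (prod_bb > prod_aa) b else a
}

# Naive O(N^2) accumulated payoff: every individual against every other.
oracle_accumulated <- function(pop, game) {
  vapply(seq_along(pop),
         function(k) sum(payoff(pop[k], pop[-k], game)),
         numeric(1))
}

# Fixed-step forward Euler integration of the replicator-mutator equation.
oracle_euler_rm <- function(x0, P, Q, t_end, dt) {
  x <- x0
  for (k in seq_len(round(t_end / dt))) {
    f <- as.vector(P %*% x)
    w <- x * f
    x <- x + dt * (as.vector(crossprod(Q, w)) - x * sum(w))
  }
  x
}

# Run a neutral Wright-Fisher population until fixation, returning the
# surviving claim.
run_to_fixation <- function(pop, game, max_gen = 5000) {
  P <- payoff_matrix(game)
  for (gen in seq_len(max_gen)) {
    if (length(unique(pop)) == 1) return(pop[1])
    pop <- wf_step(pop, game, mu = 0, delta = 1, rho = 0, P = P)
  }
  stop("no fixation within max_gen")
}
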