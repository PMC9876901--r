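test_that("Fermi acceptance probability is exact, stable and complementary", {
  expect_equal(fermi_probability(5, 5, 0.7), 0.5)
  expect_equal(fermi_probability(17, -4, 0), 0.5)
  expect_equal(fermi_probability(log(3), 0, 1), 0.75)
  # numerically stable far into both tails
  expect_equal(fermi_probability(1e4, 0, 10), 1)
  expect_equal(fermi_probability(0, 1e4, 10), 0)
  # complement identity p(a,b) + p(b,a) = 1
  set.seed(8)
  a <- stats::rnorm(20, sd = 50); b <- stats::rnorm(20, sd = 50)
  expect_equal(fermi_probability(a, b, 0.3) + fermi_probability(b, a, 0.3),
               rep(1, 20))
  expect_error(fermi_probability(1, 2, -1), ">= 0")
})

test_that("the joint chain is row-stochastic with bounded sparsity", {
  g <- td_game(2, 11, 3)
  A <- g$n_actions
  chain <- build_transition_matrix(g, beta = 0.8)
  M <- chain$transition
  expect_identical(dim(M), as.integer(c(A^2, A^2)))
  expect_equal(Matrix::rowSums(M), rep(1, A^2), tolerance = 1e-12)
  # at most 2(A - 1) admissible single-coordinate moves per state
  offdiag <- M; Matrix::diag(offdiag) <- 0
  trip <- methods::as(Matrix::drop0(offdiag), "TsparseMatrix")
  per_row <- tabulate(trip@i + 1L, nbins = A^2)
  expect_true(all(per_row <= 2 * (A - 1)))
  expect_true(all(M@x >= 0))
})

test_that("at beta = 0 every admissible single-player move is equally likely", {
  g <- td_game(2, 6, 2)
  A <- g$n_actions
  M <- build_transition_matrix(g, beta = 0)$transition
  offdiag <- as.matrix(M); diag(offdiag) <- 0
  moves <- offdiag[offdiag != 0]
  # 1/2 player choice * 1/A proposal * 1/2 Fermi acceptance
  expect_equal(moves, rep(1 / (4 * A), length(moves)))
})

test_that("beta = 0 stationary distribution is uniform over all claim pairs", {
  g <- td_game(2, 8, 2)
  A <- g$n_actions
  sd0 <- stationary_distribution(build_transition_matrix(g, beta = 0))
  expect_equal(sd0$v, rep(1 / A^2, A^2), tolerance = 1e-10)
  expect_equal(sd0$c_avg, mean(g$claims))
})

test_that("lumped solve, power iteration and a long trajectory all agree", {
  g <- td_game(2, 6, 2)
  A <- g$n_actions
  for (beta in c(0, 0.5, 1)) {
    chain <- build_transition_matrix(g, beta)
    direct <- stationary_distribution(chain, method = "lumped")
    power <- stationary_distribution(chain, method = "power", tol = 1e-12)
    expect_lt(max(abs(direct$v - power$v)), 1e-9)
    expect_lt(direct$residual, 1e-10)
    # player-exchange symmetry of the stationary law
    V <- matrix(direct$v, A, A)
    expect_equal(V, t(V), tolerance = 1e-10)
  }
  # empirical state occupancy of a 10^7-step trajectory
  chain <- build_transition_matrix(g, beta = 1)
  exact <- stationary_distribution(chain)
  sim <- simulate_trajectory(g, beta = 1, steps = 1e7, seed = 31)
  state <- (claim_to_index(sim$claims[, "n2"], g) - 1L) * A +
    claim_to_index(sim$claims[, "n1"], g)
  emp <- tabulate(state, nbins = A^2) / length(state)
  tv <- 0.5 * sum(abs(emp - exact$v))
  expect_lt(tv, 0.01)
})

test_that("stationary summaries match hand-computable cases", {
  g <- td_game(2, 100, 2)
  A <- g$n_actions
  # uniform distribution: mean claim 51
  s <- summarize_stationary(rep(1 / A^2, A^2), g)
  expect_equal(s$c_avg, 51)
  # point mass on (2, 2)
  v <- numeric(A^2); v[1] <- 1
  s2 <- summarize_stationary(v, g)
  expect_equal(s2$c_avg, 2)
  expect_equal(s2$avg_payoff, 2)
  # marginals sum to one and are claim-indexed
  expect_equal(sum(s$marginal), 1)
})

test_that("strong selection with a large reward locks the players on the Nash claim", {
  g <- td_game(2, 100, 30)
  sd <- stationary_distribution(build_transition_matrix(g, beta = 1))
  expect_lt(sd$c_avg, 2.5)
})

test_that("stationary mean claim is non-increasing in the reward at beta = 1", {
  cavg <- vapply(c(2, 5, 10, 20, 40), function(R) {
    g <- td_game(2, 100, R)
    stationary_distribution(build_transition_matrix(g, beta = 1))$c_avg
  }, numeric(1))
  expect_true(all(diff(cavg) < 0))
  expect_gt(cavg[1], 90)
})

test_that("trajectories visit the right regions in the two selection regimes", {
  g <- td_game(2, 100, 2)
  # strong selection: oscillation in the high-claim region
  strong <- simulate_trajectory(g, beta = 1, steps = 1e5, seed = 7)
  expect_gt(mean(strong$claims[-(1:1e4), ]), 80)
  # weak selection: wanders over the whole action space
  weak <- simulate_trajectory(g, beta = 0.1, steps = 1e5, seed = 7)
  occupied <- table(cut(as.vector(weak$claims[-(1:1e4), ]),
                        breaks = seq(1.5, 100.5, length.out = 11)))
  expect_true(all(occupied > 0))
  # reproducibility under the seed
  again <- simulate_trajectory(g, beta = 1, steps = 1e5, seed = 7)
  expect_identical(strong$claims, again$claims)
})

test_that("introspection on an embedded Prisoner's Dilemma ends in mutual defection", {
  # two adjacent claims with R = 2 form the local Prisoner's Dilemma;
  # strong selection concentrates the stationary law on mutual play of the
  # lower claim
  g <- td_game(2, 3, 2)
  sd <- stationary_distribution(build_transition_matrix(g, beta = 10))
  V <- matrix(sd$v, 2, 2)
  expect_gt(V[1, 1], 0.9)
})
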