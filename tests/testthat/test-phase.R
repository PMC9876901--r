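# synthetic phase grid whose Nash region is exactly {second axis > rule(first)}
synthetic_grid <- function(rule, a1, a2, axes = c("q", "R"),
                           high = 90, low = 2) {
  cells <- expand.grid(x1 = a1, x2 = a2)
  val <- ifelse(cells$x2 > rule(cells$x1), low, high)
  grid <- stats::setNames(
    data.frame(cells$x1, cells$x2, val, val),
    c(axes, "c_high_freq", "c_avg"))
  structure(grid, axes = axes, class = c("phase_grid", "data.frame"))
}

test_that("boundary detection recovers a known monotone rule within one grid cell", {
  qs <- seq(0.05, 0.9, length.out = 18)
  Rs <- seq(2, 50, length.out = 25)
  cell <- diff(Rs)[1]
  for (rule in list(function(q) 30 * sqrt(q), function(q) 10 + 25 * q)) {
    grid <- synthetic_grid(rule, qs, Rs)
    b <- detect_boundary(grid, value = "c_high_freq", threshold = 3)
    expect_equal(nrow(b), length(qs))
    expect_true(all(abs(b$boundary - rule(b$q)) <= cell))
  }
})

test_that("an all-Nash grid yields an empty boundary", {
  grid <- synthetic_grid(function(q) -Inf, seq(0.1, 0.9, 0.1), seq(2, 10, 1))
  expect_message(
    b <- detect_boundary(grid, value = "c_high_freq", threshold = 3),
    "omitted")
  expect_equal(nrow(b), 0)
})

test_that("replicated stochastic cells are averaged before thresholding", {
  grid <- data.frame(mu = rep(c(0.1, 0.2), each = 6),
                     delta = rep(rep(c(1, 10, 20), each = 2), 2),
                     c_avg_final = c(30, 20, 3, 5, 2, 2,   # mu = 0.1
                                     50, 40, 10, 6, 2, 2)) # mu = 0.2
  b <- detect_boundary(grid, value = "c_avg_final", threshold = 4,
                       axes = c("mu", "delta"))
  # mu = 0.1: cell means 25, 4, 2 -> threshold met exactly at delta = 10;
  # mu = 0.2: cell means 45, 8, 2 -> interpolated crossing at 16 + 2/3
  expect_equal(b$boundary, c(10, 10 + (4 - 8) / (2 - 8) * 10))
})

test_that("noiseless synthetic boundaries are recovered to machine precision", {
  x <- seq(0.1, 2, length.out = 12)
  fits <- list(
    sqrt = list(y = 50 * sqrt(x), coefs = c(c = 50)),
    linear = list(y = 10 + 50 * x, coefs = c(c0 = 10, c1 = 50)),
    inverse = list(y = 9 / x, coefs = c(c = 9)),
    power = list(y = 3 * x^(-1.4), coefs = c(a = 3, b = 1.4)))
  for (form in names(fits)) {
    fit <- fit_boundary(data.frame(x = x, boundary = fits[[form]]$y), form)
    expect_equal(coef(fit), fits[[form]]$coefs, tolerance = 1e-6)
    expect_lt(fit$rms, 1e-6)
    expect_equal(predict(fit, data.frame(x = x)), fits[[form]]$y,
                 tolerance = 1e-6)
  }
})

test_that("a noisy inverse law is recovered within ten percent", {
  set.seed(17)
  beta <- seq(0.2, 2, length.out = 10)
  y <- (9 / beta) * (1 + stats::rnorm(10, sd = 0.05))
  fit <- fit_boundary(data.frame(beta = beta, boundary = y), "inverse")
  expect_equal(unname(coef(fit)["c"]), 9, tolerance = 0.1)
})

test_that("degenerate fits are refused", {
  expect_error(fit_boundary(data.frame(x = 1:4, boundary = 1:4), "sqrt"),
               "at least 5 points")
  expect_error(fit_boundary(data.frame(x = rep(2, 6), boundary = 1:6), "linear"),
               "degenerate")
})

test_that("sweeps carry complete grids with their axes", {
  grid <- rm_sweep(q_values = c(0.05, 0.5), R_values = c(2, 20),
                   L = 2, U = 10)
  expect_identical(attr(grid, "axes"), c("q", "R"))
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$converged))
  # high mutation keeps high claims alive; high reward kills them
  expect_gt(grid$c_avg[grid$q == 0.5 & grid$R == 2], 5)
  expect_lt(grid$c_avg[grid$q == 0.05 & grid$R == 20], 4)

  wf <- wf_sweep(mu_values = c(0.05, 0.9), delta_values = c(1, 6),
                 rho = 0.1, R = 2, L = 2, U = 10, N = 30, t = 50,
                 replicates = 2, seed = 4)
  expect_equal(nrow(wf), 8)
  expect_identical(attr(wf, "axes"), c("mu", "delta"))
  # identical master seed reproduces the whole sweep
  wf2 <- wf_sweep(mu_values = c(0.05, 0.9), delta_values = c(1, 6),
                  rho = 0.1, R = 2, L = 2, U = 10, N = 30, t = 50,
                  replicates = 2, seed = 4)
  expect_identical(wf$c_avg_final, wf2$c_avg_final)

  intro <- introspection_sweep(beta_values = c(0.5, 1),
                               R_values = list(c(2, 3), c(2, 3, 4)),
                               L = 2, U = 8)
  expect_equal(nrow(intro), 5)
  expect_true(all(c("c_avg", "c_high_freq") %in% names(intro)))
})

test_that("cross-model concordance: higher rewards shrink the cooperative region", {
  # replicator-mutator: the reward at which the Nash regime takes over
  # rises with the mutation strength, i.e. more diversity sustains
  # cooperation against larger rewards
  qs <- seq(0.1, 0.85, length.out = 8)
  Rs <- seq(2, 12, length.out = 11)
  grid <- rm_sweep(qs, Rs, L = 2, U = 10)
  b <- detect_boundary(grid, value = "c_high_freq", threshold = 3)
  expect_gt(nrow(b), 4)
  expect_true(all(diff(b$boundary) >= 0))
  # introspection shows the same direction: at fixed selection intensity
  # the stationary mean claim falls as the reward grows (exact solves on a
  # reduced action space)
  cavg <- vapply(c(2, 4, 6), function(R) {
    g <- td_game(2, 10, R)
    stationary_distribution(build_transition_matrix(g, beta = 1))$c_avg
  }, numeric(1))
  expect_true(all(diff(cavg) < 0))
})
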