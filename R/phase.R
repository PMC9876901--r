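#' Replicator-mutator phase sweep over mutation strength and reward
#'
#' Integrates the replicator-mutator dynamics to equilibrium from a uniform
#' start for every combination of `q` and `R` and records the equilibrium
#' summaries.
#'
#' @param q_values Mutation strengths.
#' @param R_values Reward values (each `> 1`).
#' @param L,U Claim bounds.
#' @param ... Passed to [replicator_mutator()] (e.g. `t_max`, `tol`).
#' @return A data.frame of class `"phase_grid"` with columns `q`, `R`,
#'   `c_high_freq`, `c_avg`, `avg_payoff`, `converged`; attribute `axes`
#'   is `c("q", "R")`.
#' @export
rm_sweep <- function(q_values, R_values, L = 2, U = 100, ...) {
  cells <- expand.grid(q = q_values, R = R_values)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    g <- td_game(L, U, cells$R[k])
    eq <- replicator_mutator(g, q = cells$q[k], ...)
    data.frame(q = cells$q[k], R = cells$R[k],
               c_high_freq = eq$c_high_freq, c_avg = eq$c_avg,
               avg_payoff = eq$avg_payoff, converged = eq$converged)
  })
  grid <- do.call(rbind, res)
  structure(grid, axes = c("q", "R"), class = c("phase_grid", "data.frame"))
}

#' Wright-Fisher phase sweep over mutation probability and size
#'
#' Runs replicated Wright-Fisher simulations on a `mu x delta` grid. Child
#' seeds are derived deterministically from `seed` and the cell/replicate
#' index, so a sweep is reproducible as a whole.
#'
#' @param mu_values Mutation probabilities.
#' @param delta_values Maximal mutation sizes.
#' @param rho Selection intensity.
#' @param R Reward value.
#' @param L,U Claim bounds.
#' @param N Population size.
#' @param t Generations per run.
#' @param replicates Independent runs per cell.
#' @param seed Master seed for the sweep.
#' @param ... Passed to [wright_fisher()].
#' @return A data.frame of class `"phase_grid"`, one row per replicate, with
#'   columns `mu`, `delta`, `rho`, `R`, `seed`, `c_avg_final`; attribute
#'   `axes` is `c("mu", "delta")`.
#' @export
wf_sweep <- function(mu_values, delta_values, rho, R = 2, L = 2, U = 100,
                     N = 100, t = 1000, replicates = 10, seed = 1, ...) {
  g <- td_game(L, U, R)
  cells <- expand.grid(mu = mu_values, delta = delta_values)
  res <- vector("list", nrow(cells) * replicates)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      child <- (seed * 1000003L + ci * 1009L + rep_i) %% 2147483647L
      run <- wright_fisher(g, N = N, mu = cells$mu[ci],
                           delta = cells$delta[ci], rho = rho, t = t,
                           seed = child, ...)
      res[[k]] <- data.frame(mu = cells$mu[ci], delta = cells$delta[ci],
                             rho = rho, R = R, seed = child,
                             c_avg_final = run$c_avg_final)
    }
  }
  grid <- do.call(rbind, res)
  structure(grid, axes = c("mu", "delta"), class = c("phase_grid", "data.frame"))
}

#' Introspection phase sweep over selection intensity and reward
#'
#' Computes the exact stationary distribution for every `(beta, R)`
#' combination. `R_values` may be a list named by `beta` value to use a
#' different reward scan per selection intensity (the boundary location
#' scales roughly like `1/beta`, so matched scans keep sweeps affordable).
#'
#' @param beta_values Selection intensities.
#' @param R_values Reward values, or a list of reward vectors with one
#'   element per `beta`.
#' @param L,U Claim bounds.
#' @param ... Passed to [stationary_distribution()].
#' @return A data.frame of class `"phase_grid"` with columns `beta`, `R`,
#'   `c_avg`, `c_high_freq` (modal claim of the stationary marginal),
#'   `avg_payoff`; attribute `axes` is `c("beta", "R")`.
#' @export
introspection_sweep <- function(beta_values, R_values, L = 2, U = 100, ...) {
  if (!is.list(R_values))
    R_values <- rep(list(R_values), length(beta_values))
  if (length(R_values) != length(beta_values))
    stop("R_values must be a vector or a list with one element per beta")
  res <- list()
  for (bi in seq_along(beta_values)) {
    beta <- beta_values[bi]
    for (R in R_values[[bi]]) {
      g <- td_game(L, U, R)
      chain <- build_transition_matrix(g, beta)
      sd <- stationary_distribution(chain, ...)
      res[[length(res) + 1L]] <-
        data.frame(beta = beta, R = R, c_avg = sd$c_avg,
                   c_high_freq = g$claims[which.max(sd$marginal)],
                   avg_payoff = sd$avg_payoff)
    }
  }
  grid <- do.call(rbind, res)
  structure(grid, axes = c("beta", "R"), class = c("phase_grid", "data.frame"))
}

#' Detect the Nash-regime boundary in a phase grid
#'
#' For each value of the first axis, finds the smallest second-axis value at
#' which the chosen summary first drops to the Nash regime
#' (`value <= threshold`), interpolating linearly between the bracketing
#' grid cells. Slices with replicated cells (stochastic sweeps) are
#' averaged per cell first. Slices without a crossing are omitted with a
#' message.
#'
#' @param grid A `"phase_grid"` data.frame (or any data.frame).
#' @param value Column to threshold: `"c_high_freq"` for the
#'   deterministic claim-with-highest-frequency criterion, `"c_avg"` (or
#'   `"c_avg_final"` for Wright-Fisher sweeps) for mean-claim criteria.
#' @param threshold Nash-regime threshold; defaults to `L + 1` for
#'   `c_high_freq` and `L + 2` for mean-claim columns, with `L` read from
#'   the smallest value in the grid's claim summaries... supply explicitly
#'   when in doubt.
#' @param axes Character vector of the two axis column names; defaults to
#'   the grid's `axes` attribute.
#' @return A data.frame with the first-axis values and the interpolated
#'   `boundary` position along the second axis.
#' @export
detect_boundary <- function(grid, value = c("c_high_freq", "c_avg",
                                            "c_avg_final"),
                            threshold = NULL, axes = attr(grid, "axes")) {
  value <- match.arg(value)
  if (is.null(axes) || length(axes) != 2)
    stop("supply `axes`: the two parameter column names")
  if (!all(c(axes, value) %in% names(grid)))
    stop("grid lacks the requested axis or value columns")
  if (is.null(threshold)) {
    Lguess <- min(grid[[value]])
    threshold <- if (value == "c_high_freq") Lguess + 1 else Lguess + 2
  }
  a1 <- axes[1]; a2 <- axes[2]
  out <- list()
  for (v1 in sort(unique(grid[[a1]]))) {
    sl <- grid[grid[[a1]] == v1, c(a2, value)]
    # average replicates per cell
    sl <- stats::aggregate(sl[[value]], by = list(x = sl[[a2]]), FUN = mean)
    sl <- sl[order(sl$x), ]
    idx <- which(sl[, 2] <= threshold)[1]
    if (is.na(idx) || idx == 1) {
      # either never Nash, or Nash already at the smallest grid value:
      # no transition to locate on this slice
      message(sprintf("no Nash-regime crossing along %s = %g; slice omitted",
                      a1, v1))
      next
    }
    x1 <- sl$x[idx - 1]; x2 <- sl$x[idx]
    y1 <- sl[idx - 1, 2]; y2 <- sl[idx, 2]
    b <- x1 + (threshold - y1) / (y2 - y1) * (x2 - x1)
    out[[length(out) + 1L]] <- stats::setNames(
      data.frame(v1, b), c(a1, "boundary"))
  }
  if (length(out) == 0)
    return(stats::setNames(data.frame(numeric(0), numeric(0)),
                           c(a1, "boundary")))
  do.call(rbind, out)
}

#' Fit a boundary curve to detected phase-boundary points
#'
#' Unweighted least squares in the untransformed coordinates for one of the
#' canonical boundary forms: `sqrt` (`y = c * sqrt(x)`), `linear`
#' (`y = c1 * x + c0`), `inverse` (`y = c / x`) and `power`
#' (`y = a * x^(-b)`, fitted by Gauss-Newton from a log-log start).
#'
#' @param points A data.frame of boundary points (as from
#'   [detect_boundary()]): first column the abscissa, column `boundary` (or
#'   the second column) the ordinate. At least 5 points are required.
#' @param form One of `"sqrt"`, `"linear"`, `"inverse"`, `"power"`.
#' @return An object of class `"boundary_fit"`: list with `form`,
#'   `coefficients`, `fitted`, `residuals`, `rms`, `points`, `n`. Methods:
#'   `print`, `coef`, `predict(object, newdata = data.frame(x = ...))`,
#'   `residuals`.
#' @examples
#' pts <- data.frame(q = seq(0.1, 0.9, length.out = 9),
#'                   boundary = 50 * sqrt(seq(0.1, 0.9, length.out = 9)))
#' coef(fit_boundary(pts, "sqrt")) # c = 50
#' @export
fit_boundary <- function(points, form = c("sqrt", "linear", "inverse", "power")) {
  form <- match.arg(form)
  if (!is.data.frame(points) || ncol(points) < 2)
    stop("points must be a data.frame with abscissa and boundary columns")
  x <- points[[1]]
  y <- if ("boundary" %in% names(points)) points$boundary else points[[2]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("boundary fit requires at least 5 points")

  cf <- switch(form,
    sqrt = {
      cc <- sum(y * sqrt(x)) / sum(x)
      c(c = cc)
    },
    linear = {
      fit <- stats::lm(y ~ x)
      c(c0 = unname(stats::coef(fit)[1]), c1 = unname(stats::coef(fit)[2]))
    },
    inverse = {
      cc <- sum(y / x) / sum(1 / x^2)
      c(c = cc)
    },
    power = {
      if (any(x <= 0) || any(y <= 0))
        stop("power-form fit needs positive coordinates")
      ll <- stats::lm(log(y) ~ log(x))
      start <- list(a = exp(unname(stats::coef(ll)[1])),
                    b = -unname(stats::coef(ll)[2]))
      start_rss <- sum((y - start$a * x^(-start$b))^2)
      if (start_rss < 1e-14 * sum(y^2)) {
        # log-log fit already interpolates (noiseless data); nls cannot
        # improve a zero-residual problem
        c(a = start$a, b = start$b)
      } else {
        fit <- tryCatch(
          stats::nls(y ~ a * x^(-b), start = start,
                     control = stats::nls.control(warnOnly = TRUE)),
          error = function(e) NULL)
        if (is.null(fit)) c(a = start$a, b = start$b)
        else c(a = unname(stats::coef(fit)["a"]),
               b = unname(stats::coef(fit)["b"]))
      }
    })

  fitted <- boundary_form_eval(form, cf, x)
  resid <- y - fitted
  qr_ok <- stats::sd(x) > 0
  if (!qr_ok) stop("degenerate fit: abscissa values are constant")
  structure(
    list(form = form, coefficients = cf, fitted = fitted, residuals = resid,
         rms = sqrt(mean(resid^2)), points = data.frame(x = x, y = y),
         n = length(x)),
    class = "boundary_fit"
  )
}

boundary_form_eval <- function(form, cf, x) {
  switch(form,
    sqrt = cf[["c"]] * sqrt(x),
    linear = cf[["c0"]] + cf[["c1"]] * x,
    inverse = cf[["c"]] / x,
    power = cf[["a"]] * x^(-cf[["b"]]))
}

#' @export
print.boundary_fit <- function(x, ...) {
  lab <- switch(x$form,
    sqrt = "y = c * sqrt(x)", linear = "y = c0 + c1 * x",
    inverse = "y = c / x", power = "y = a * x^(-b)")
  cat(sprintf("Boundary fit: %s  (%d points)\n", lab, x$n))
  cat("  coefficients: ",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  RMS residual: %.4g\n", x$rms))
  invisible(x)
}

#' @export
coef.boundary_fit <- function(object, ...) object$coefficients

#' @export
residuals.boundary_fit <- function(object, ...) object$residuals

#' @export
predict.boundary_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x else newdata[[1]]
  boundary_form_eval(object$form, object$coefficients, x)
}

#' @export
plot.boundary_fit <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y, xlab = "axis 1", ylab = "boundary",
                 main = sprintf("boundary fit (%s)", x$form), ...)
  xx <- seq(min(x$points$x), max(x$points$x), length.out = 200)
  graphics::lines(xx, boundary_form_eval(x$form, x$coefficients, xx))
  invisible(x)
}
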