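#' Define a Traveler's Dilemma game
#'
#' Constructs the specification of a Traveler's Dilemma: each of two players
#' claims an integer in `[L, U]`, equal claims are paid out as claimed, and
#' when the claims differ the lower claimant receives their claim plus the
#' reward `R` while the higher claimant receives the lower claim minus `R`.
#'
#' @param L Integer lower claim bound, `0 <= L < U`.
#' @param U Integer upper claim bound.
#' @param R Reward parameter, `R > 1`. Payoff units are claim units.
#'
#' @return An object of class `"td_game"`: a list with elements `L`, `U`,
#'   `R`, `claims` (the action space `L:U`) and `n_actions`.
#'
#' @examples
#' g <- td_game(L = 2, U = 100, R = 2)
#' g$n_actions # 99 possible claims
#' @export
td_game <- function(L = 2, U = 100, R = 2) {
  if (length(L) != 1 || length(U) != 1 || length(R) != 1)
    stop("L, U and R must be scalars")
  if (!is.finite(L) || !is.finite(U) || !is.finite(R))
    stop("L, U and R must be finite")
  if (L != round(L) || U != round(U))
    stop("claim bounds L and U must be integers")
  if (!(0 <= L && L < U))
    stop("claim bounds must satisfy 0 <= L < U")
  if (R <= 1)
    stop("reward parameter R must exceed 1")
  L <- as.integer(L); U <- as.integer(U)
  structure(
    list(L = L, U = U, R = as.numeric(R),
         claims = L:U, n_actions = U - L + 1L),
    class = "td_game"
  )
}

#' @export
print.td_game <- function(x, ...) {
  cat("Traveler's Dilemma game\n")
  cat(sprintf("  claims: integers in [%d, %d]  (%d actions)\n",
              x$L, x$U, x$n_actions))
  cat(sprintf("  reward R = %g\n", x$R))
  cat(sprintf("  Nash equilibrium: {%d, %d}\n", x$L, x$L))
  invisible(x)
}

check_claims <- function(n, game, arg = "claim") {
  if (any(n != round(n)) || any(n < game$L) || any(n > game$U))
    stop(sprintf("%s must be an integer in [%d, %d]", arg, game$L, game$U))
  invisible(as.integer(n))
}

#' Payoff of one player against another
#'
#' The row player claiming `ni` against an opponent claiming `nj` receives
#' `ni` if the claims are equal, `ni + R` if `ni < nj`, and `nj - R` if
#' `ni > nj`.
#'
#' @param ni,nj Integer claims in `[L, U]`; vectorized (recycled).
#' @param game A [td_game()] object.
#' @return Numeric payoff(s) to the player claiming `ni`.
#' @examples
#' g <- td_game(2, 100, 2)
#' payoff(2, 2, g)    # 2
#' payoff(2, 100, g)  # 4
#' payoff(100, 2, g)  # 0
#' @export
payoff <- function(ni, nj, game) {
  check_claims(ni, game, "ni")
  check_claims(nj, game, "nj")
  ifelse(ni == nj, ni, ifelse(ni < nj, ni + game$R, nj - game$R))
}

#' Full payoff matrix of the game
#'
#' @param game A [td_game()] object.
#' @return A square numeric matrix of side `U - L + 1`; entry `[i, j]` is the
#'   payoff of the row player claiming the i-th claim against the column
#'   player claiming the j-th. Dimnames are the claim values.
#' @examples
#' payoff_matrix(td_game(2, 3, 2)) # matrix(c(2, 0, 4, 3), 2)
#' @export
payoff_matrix <- function(game) {
  cl <- game$claims
  P <- outer(cl, cl, function(a, b)
    ifelse(a == b, a, ifelse(a < b, a + game$R, b - game$R)))
  dimnames(P) <- list(cl, cl)
  P
}

#' Convert between claims and matrix indices
#'
#' Index 1 corresponds to claim `L`.
#'
#' @param claim Integer claim(s) in `[L, U]`.
#' @param index Integer index(es) in `1:n_actions`.
#' @param game A [td_game()] object.
#' @return Integer vector of indices, resp. claims.
#' @export
claim_to_index <- function(claim, game) {
  check_claims(claim, game)
  as.integer(claim) - game$L + 1L
}

#' @rdname claim_to_index
#' @export
index_to_claim <- function(index, game) {
  if (any(index < 1L) || any(index > game$n_actions))
    stop("index out of range")
  game$L + as.integer(index) - 1L
}

#' Classify a pair of claims as a local or global sub-game
#'
#' Restricting the Traveler's Dilemma to two claims `n` and `n + s` yields a
#' 2x2 symmetric game. For `1 <= s <= R - 1` this restriction has the
#' structure of a Prisoner's Dilemma (the "local" game: the lower claim
#' strictly dominates, yet mutual play of the higher claim Pareto-dominates).
#' For `s >= R` it is a coordination game (the "global" game: both diagonal
#' profiles are Nash), whose payoff-dominant equilibrium is the higher claim
#' and whose risk-dominant equilibrium follows the Harsanyi-Selten criterion:
#' in a symmetric 2x2 game, action b risk-dominates a iff
#' `pi(b,b) + pi(b,a) > pi(a,a) + pi(a,b)`, which here reduces to `s > 2 R`
#' for the higher claim.
#'
#' For non-integer `R` with `R - 1 < s < R` the two stated ranges leave a
#' gap; such pairs are classified by direct best-response analysis of the
#' 2x2 restriction.
#'
#' @param n Integer base claim.
#' @param s Positive integer claim separation; `n + s` must lie in `[L, U]`.
#' @param game A [td_game()] object.
#' @return A list of class `"pair_game_class"` with elements `kind` (one of
#'   `"prisoners_dilemma"`, `"coordination"`, `"other"`),
#'   `payoff_dominant_action` and `risk_dominant_action` (claims, `NA` for
#'   the Prisoner's Dilemma case, where the only equilibrium is mutual play
#'   of `n`), and the 2x2 `submatrix`.
#' @examples
#' g <- td_game(2, 100, 2)
#' classify_pair(2, 1, g)$kind  # "prisoners_dilemma"
#' classify_pair(2, 98, g)      # coordination; 100 payoff and risk dominant
#' @export
classify_pair <- function(n, s, game) {
  if (length(n) != 1 || length(s) != 1) stop("n and s must be scalars")
  if (s < 1 || s != round(s)) stop("s must be a positive integer")
  check_claims(n, game, "n")
  check_claims(n + s, game, "n + s")
  R <- game$R
  M <- matrix(c(payoff(n, n, game),     payoff(n, n + s, game),
                payoff(n + s, n, game), payoff(n + s, n + s, game)),
              2, 2, byrow = TRUE,
              dimnames = list(c(n, n + s), c(n, n + s)))

  if (s <= R - 1) {
    kind <- "prisoners_dilemma"
    pd <- NA_integer_; rd <- NA_integer_
  } else if (s >= R) {
    kind <- "coordination"
    pd <- as.integer(n + s)
    # Harsanyi-Selten for symmetric 2x2: higher claim risk dominates iff s > 2R
    rd <- if (M[2, 2] + M[2, 1] > M[1, 1] + M[1, 2]) as.integer(n + s)
          else as.integer(n)
  } else {
    # non-integer R gap: fall back to best-response analysis
    cls <- analyze_2x2(M)
    kind <- cls$kind
    pd <- cls$payoff_dominant
    rd <- cls$risk_dominant
  }
  structure(list(kind = kind,
                 payoff_dominant_action = pd,
                 risk_dominant_action = rd,
                 n = as.integer(n), s = as.integer(s),
                 submatrix = M),
            class = "pair_game_class")
}

# Best-response analysis of a symmetric 2x2 game with payoff matrix M for the
# row player (actions labelled by dimnames). PD: one action strictly
# dominates but the dominated diagonal Pareto-dominates the equilibrium.
# Coordination: both diagonal profiles are strict Nash equilibria.
analyze_2x2 <- function(M) {
  acts <- as.integer(rownames(M))
  dom1 <- M[1, 1] > M[2, 1] && M[1, 2] > M[2, 2] # action 1 strictly dominates
  dom2 <- M[2, 1] > M[1, 1] && M[2, 2] > M[1, 2]
  nash11 <- M[1, 1] >= M[2, 1]
  nash22 <- M[2, 2] >= M[1, 2]
  if (nash11 && nash22 && !dom1 && !dom2) {
    pd <- acts[which.max(c(M[1, 1], M[2, 2]))]
    rd <- if (M[2, 2] + M[2, 1] > M[1, 1] + M[1, 2]) acts[2] else acts[1]
    list(kind = "coordination", payoff_dominant = pd, risk_dominant = rd)
  } else if ((dom1 && M[2, 2] > M[1, 1]) || (dom2 && M[1, 1] > M[2, 2])) {
    list(kind = "prisoners_dilemma",
         payoff_dominant = NA_integer_, risk_dominant = NA_integer_)
  } else {
    list(kind = "other",
         payoff_dominant = NA_integer_, risk_dominant = NA_integer_)
  }
}

#' @export
print.pair_game_class <- function(x, ...) {
  cat(sprintf("claims {%d, %d}: %s\n", x$n, x$n + x$s, x$kind))
  if (x$kind == "coordination")
    cat(sprintf("  payoff dominant: %d, risk dominant: %d\n",
                x$payoff_dominant_action, x$risk_dominant_action))
  invisible(x)
}
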