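#' Mean payoffs of cooperators and defectors under fast linking
#'
#' Under time-scale separation (strategy updates much rarer than linking
#' events) the network is in the stationary regime of the linking dynamics
#' whenever a strategy changes, so the expected stationary link counts
#' determine average payoffs. Each of the `L*pi_CC` CC links pays `R` to two
#' cooperators; each CD link pays `S` to its cooperator and `T` to its
#' defector; each DD link pays `P` to two defectors. Dividing the total
#' payoff flowing to each strategy by the number of its players gives
#' \deqn{f_C = (2 L \pi_{CC} R + L \pi_{CD} S) / (N x)}
#' \deqn{f_D = (2 L \pi_{DD} P + L \pi_{CD} T) / (N (1 - x)).}
#'
#' @param x Cooperator frequency, strictly inside (0, 1); vectorized.
#' @param game A [game_params()] object.
#' @param k A [link_break_probs()] object.
#' @param N Population size.
#' @param L Number of links.
#' @return A list with numeric vectors `f_c` and `f_d` (same length as `x`).
#' @examples
#' mean_payoffs(0.5, game_params(b = 0.5), link_break_probs(0.2, 0.8, 0.4),
#'              N = 100, L = 500)
#' @export
mean_payoffs <- function(x, game, k, N, L) {
  k <- as_link_break_probs(k)
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("`x` must lie strictly inside (0, 1); take boundary limits explicitly",
         call. = FALSE)
  }
  w_cc <- x^2 / k$k_cc
  w_cd <- 2 * x * (1 - x) / k$k_cd
  w_dd <- (1 - x)^2 / k$k_dd
  tot <- w_cc + w_cd + w_dd
  pi_cc <- w_cc / tot; pi_cd <- w_cd / tot; pi_dd <- w_dd / tot
  f_c <- (2 * L * pi_cc * game$R + L * pi_cd * game$S) / (N * x)
  f_d <- (2 * L * pi_dd * game$P + L * pi_cd * game$T) / (N * (1 - x))
  list(f_c = f_c, f_d = f_d)
}

#' The transformed game induced by the linking dynamics
#'
#' Weighting each payoff entry by the stationary abundance of the link type
#' that delivers it is, up to a positive common factor, equivalent to
#' dividing each entry of the original matrix by the breaking probability of
#' that link type: `R' = R/k_CC`, `S' = S/k_CD`, `T' = T/k_CD`,
#' `P' = P/k_DD`. The selection gradient `f_C - f_D` of [mean_payoffs()] is
#' proportional to the replicator gradient of this transformed matrix, so
#' equilibria and stability carry over exactly (the dropped prefactor is
#' always positive). When `R' > T'` and `P' > S'` the transformed game is a
#' coordination game: the Prisoner's Dilemma has been turned into a game
#' where full cooperation is stable.
#'
#' @param game A [game_params()] object.
#' @param k A [link_break_probs()] object with all entries > 0.
#' @return A 2x2 matrix in the layout of [build_payoff_matrix()].
#' @examples
#' transformed_game(game_params(b = 0.5), link_break_probs(0.2, 0.8, 0.4))
#' @export
transformed_game <- function(game, k) {
  k <- as_link_break_probs(k)
  if (k$k_cc <= 0 || k$k_cd <= 0 || k$k_dd <= 0) {
    stop("all breaking probabilities must be > 0", call. = FALSE)
  }
  matrix(c(game$R / k$k_cc, game$T / k$k_cd,
           game$S / k$k_cd, game$P / k$k_dd),
         nrow = 2, dimnames = list(c("C", "D"), c("C", "D")))
}

#' Fragility index of mixed links
#'
#' `g = k_CD/k_CC - 1` compares the fragility of cooperator-defector links
#' to cooperator-cooperator links: `g > 0` means mixed links are more
#' fragile, so cooperators preferentially keep ties with cooperators and
#' cluster. The stability rule for cooperation is `g > b`; it involves only
#' this ratio and is independent of `k_DD`.
#'
#' @param k A [link_break_probs()] object with `k_cc > 0`.
#' @return The fragility index, a single number.
#' @examples
#' fragility_index(link_break_probs(0.2, 0.8, 0.4))
#' @export
fragility_index <- function(k) {
  k <- as_link_break_probs(k)
  if (k$k_cc <= 0) stop("`k_cc` must be > 0", call. = FALSE)
  k$k_cd / k$k_cc - 1
}

#' Is full cooperation stable under the linking dynamics?
#'
#' Cooperation is stable when the transformed game is a coordination game
#' with cooperation a best reply to itself: `R' > T'` (for the
#' one-parameter game, exactly `g > b`, i.e. `k_CD > (1 + b) k_CC`) and
#' `P' > S'`. Strict inequalities: the boundary `g = b` counts as unstable.
#' Equivalent to `f_C > f_D` in the `x -> 1` limit.
#'
#' @inheritParams transformed_game
#' @return `TRUE` or `FALSE`.
#' @export
cooperation_stable <- function(game, k) {
  m <- transformed_game(game, k)
  (m["C", "C"] > m["D", "C"]) && (m["D", "D"] > m["C", "D"])
}

#' Interior (unstable) equilibrium of the cooperator frequency
#'
#' The cooperator frequency `x*` at which average cooperator and defector
#' payoffs coincide, i.e. the interior root of the replicator dynamics of
#' the transformed game:
#' \deqn{x^* = (P' - S') / (P' - S' + R' - T').}
#' For the one-parameter game this reduces to
#' `x* = b / (b + (g - b) k_DD / k_CD)`. The root lies in (0, 1) exactly
#' when [cooperation_stable()] holds; otherwise `NA` is returned (defection
#' dominates throughout). `x*` is unstable: initial cooperator frequencies
#' above it reach full cooperation, those below it reach full defection, so
#' `1 - x*` is the size of the basin of attraction of cooperation.
#'
#' @inheritParams transformed_game
#' @return `x*` in (0, 1), or `NA_real_` when no interior equilibrium exists.
#' @examples
#' interior_equilibrium(game_params(b = 0.5), link_break_probs(0.2, 0.8, 0.4))
#' @export
interior_equilibrium <- function(game, k) {
  m <- transformed_game(game, k)
  if (!cooperation_stable(game, k)) return(NA_real_)
  num <- m["D", "D"] - m["C", "D"]          # P' - S'
  den <- num + (m["C", "C"] - m["D", "C"])  # + (R' - T')
  num / den
}

#' Analytic summary of a parameter configuration
#'
#' Bundles the closed-form results for one game and one triple of breaking
#' probabilities: the fragility index `g`, the stability flag, the interior
#' equilibrium `x*` (when it exists), the basin of attraction of cooperation
#' `1 - x*`, and the transformed payoff matrix.
#'
#' @inheritParams transformed_game
#' @return An object of class `analytic_summary`: list with `g`, `x_star`,
#'   `cooperation_stable`, `basin_size`, `transformed`, `game`, `k`.
#' @examples
#' analytic_summary(game_params(b = 0.5), link_break_probs(0.2, 0.8, 0.4))
#' @export
analytic_summary <- function(game, k) {
  k <- as_link_break_probs(k)
  stable <- cooperation_stable(game, k)
  x_star <- interior_equilibrium(game, k)
  structure(list(
    g = fragility_index(k),
    x_star = x_star,
    cooperation_stable = stable,
    basin_size = if (stable) 1 - x_star else 0,
    transformed = transformed_game(game, k),
    game = game, k = k), class = "analytic_summary")
}

#' @export
print.analytic_summary <- function(x, ...) {
  cat("Linking-dynamics analysis\n")
  cat(sprintf("  fragility index g = %.4f\n", x$g))
  if (x$cooperation_stable) {
    cat(sprintf("  cooperation STABLE: interior equilibrium x* = %.4f,", x$x_star))
    cat(sprintf(" basin of cooperation = %.4f\n", x$basin_size))
  } else {
    cat("  cooperation UNSTABLE: defection dominates (no interior equilibrium)\n")
  }
  cat("  transformed game:\n")
  print(round(x$transformed, 4))
  invisible(x)
}

# Bisection root of f_C(x) - f_D(x) on (0, 1); independent numeric oracle
# for the closed-form x*. Returns NA when the gradient has no sign change.
payoff_balance_root <- function(game, k, tol = 1e-12) {
  f <- function(x) {
    p <- mean_payoffs(x, game, k, N = 100, L = 500)
    p$f_c - p$f_d
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  if (f(lo) * f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
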