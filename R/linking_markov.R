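#' Single-link transition matrix of the linking dynamics
#'
#' At fixed cooperator frequency `x`, the type of a single tracked link (a
#' broken link passes its identity to its replacement) evolves as a 3-state
#' Markov chain over (CC, CD, DD). Per elementary linking event the link is
#' selected with probability `1/L`; a selected link of type XY breaks with
#' probability `k_XY`; on a break the switching endpoint keeps its strategy
#' and draws a new partner who is a cooperator with probability `x`; from a
#' CD link the cooperator or the defector side switches with probability 1/2
#' each. Direct CC <-> DD transitions are impossible, so the chain is
#' birth-death.
#'
#' The matrix treats the new partner as a uniform draw from the whole
#' population at frequency `x`; it does not exclude the switching node's
#' current neighbors. The gap to the simulator (which forbids duplicate
#' links) vanishes as `N >> k`.
#'
#' @param k A [link_break_probs()] object (or coercible triple).
#' @param x Cooperator frequency in `[0, 1]`.
#' @param L Total number of links (>= 1).
#' @return A 3x3 row-stochastic matrix with dimnames
#'   `c("CC", "CD", "DD")`, rows = current type, columns = next type.
#' @examples
#' transition_matrix(link_break_probs(0.2, 0.8, 0.4), x = 0.5, L = 100)
#' @export
transition_matrix <- function(k, x, L) {
  k <- as_link_break_probs(k)
  x <- as.numeric(x)
  if (!is.finite(x) || x < 0 || x > 1) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  L <- as.numeric(L)
  if (!is.finite(L) || L < 1) stop("`L` must be at least 1", call. = FALSE)
  sel <- 1 / L
  m <- matrix(0, 3, 3, dimnames = list(c("CC", "CD", "DD"),
                                       c("CC", "CD", "DD")))
  m["CC", "CD"] <- sel * k$k_cc * (1 - x)
  m["CD", "CC"] <- sel * k$k_cd * 0.5 * x
  m["CD", "DD"] <- sel * k$k_cd * 0.5 * (1 - x)
  m["DD", "CD"] <- sel * k$k_dd * x
  diag(m) <- 1 - rowSums(m)
  m
}

#' Stationary distribution of the link-type chain
#'
#' The unique stationary distribution of [transition_matrix()] for all
#' breaking probabilities > 0 and interior `x`; it does not depend on `L`.
#' By detailed balance of the birth-death chain,
#' `pi_CC : pi_CD : pi_DD = x^2/k_CC : 2x(1-x)/k_CD : (1-x)^2/k_DD`,
#' normalized to sum 1. In the stationary regime `pi_XY` is also the average
#' fraction of XY links in the whole population at cooperator frequency `x`.
#'
#' Boundary frequencies are handled as limits: `x = 1` returns the point
#' mass on CC and `x = 0` the point mass on DD (with any `k`).
#'
#' @inheritParams transition_matrix
#' @return An object of class `link_type_distribution`: list with `pi`
#'   (named probability vector over CC, CD, DD) and `x`.
#' @examples
#' stationary_distribution(link_break_probs(0.2, 0.8, 0.4), x = 0.5)
#' @export
stationary_distribution <- function(k, x) {
  k <- as_link_break_probs(k)
  x <- as.numeric(x)
  if (!is.finite(x) || x < 0 || x > 1) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  if (x == 0 || x == 1) {
    p <- if (x == 1) c(CC = 1, CD = 0, DD = 0) else c(CC = 0, CD = 0, DD = 1)
    return(structure(list(pi = p, x = x, boundary = TRUE),
                     class = "link_type_distribution"))
  }
  if (k$k_cc <= 0 || k$k_cd <= 0 || k$k_dd <= 0) {
    stop(paste("all breaking probabilities must be > 0 for the chain to be",
               "irreducible"), call. = FALSE)
  }
  w <- c(CC = x^2 / k$k_cc,
         CD = 2 * x * (1 - x) / k$k_cd,
         DD = (1 - x)^2 / k$k_dd)
  structure(list(pi = w / sum(w), x = x, boundary = FALSE),
            class = "link_type_distribution")
}

#' @export
print.link_type_distribution <- function(x, ...) {
  cat(sprintf("Stationary link-type distribution at x = %g\n", x$x))
  print(round(x$pi, 6))
  invisible(x)
}

#' Expected stationary link counts
#'
#' The average number of links of each type in a network with `L` links once
#' the linking dynamics has reached its stationary regime.
#'
#' @param pi A `link_type_distribution` (or bare probability vector over
#'   CC, CD, DD).
#' @param L Total number of links.
#' @return Named numeric vector `c(n_cc, n_cd, n_dd)` summing to `L`.
#' @export
expected_link_counts <- function(pi, L) {
  p <- if (inherits(pi, "link_type_distribution")) pi$pi else as.numeric(pi)
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`pi` must be a probability vector over the three link types",
         call. = FALSE)
  }
  L <- as.numeric(L)
  stats::setNames(L * p, c("n_cc", "n_cd", "n_dd"))
}

# Numeric left fixed vector of a row-stochastic matrix; cross-check path
# for the closed form (eigen-based, independent of the detailed-balance
# derivation).
left_stationary_numeric <- function(m) {
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(m))
}
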