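#' Prisoner's Dilemma game parameters
#'
#' Defines the 2x2 Prisoner's Dilemma either through the one-parameter form
#' or through explicit payoff entries. In the one-parameter form the payoffs
#' are `R = 1` (mutual cooperation), `S = 0` (exploited cooperator),
#' `T = 1 + b` (unilateral defection) and `P = b` (mutual defection), so that
#' `b = T - R = P - S` measures how profitable unilateral defection is.
#' Explicit entries, when supplied, override the one-parameter form.
#'
#' Any valid game must satisfy the strict Prisoner's Dilemma ranking
#' `T > R > P > S` together with `2R > T + S` (mutual cooperation beats
#' alternation).
#'
#' @param b Temptation parameter in the open interval (0, 1). Ignored when
#'   all four explicit entries are supplied.
#' @param T,R,P,S Optional explicit payoff entries (temptation, reward,
#'   punishment, sucker). Either all four or none must be given.
#' @return An object of class `game_params` with elements `T`, `R`, `P`, `S`
#'   and, in the one-parameter form, `b`.
#' @examples
#' game_params(b = 0.5)
#' game_params(T = 5, R = 3, P = 1, S = 0)
#' @export
game_params <- function(b = NULL, T = NULL, R = NULL, P = NULL, S = NULL) {
  explicit <- list(T = T, R = R, P = P, S = S)
  n_given <- sum(!vapply(explicit, is.null, logical(1)))
  if (n_given > 0 && n_given < 4) {
    stop("explicit payoffs require all four of T, R, P, S", call. = FALSE)
  }
  if (n_given == 4) {
    vals <- vapply(explicit, as.numeric, numeric(1))
    if (any(!is.finite(vals))) {
      stop("payoff entries must be finite", call. = FALSE)
    }
    check_pd_ranking(vals[["T"]], vals[["R"]], vals[["P"]], vals[["S"]])
    out <- list(T = vals[["T"]], R = vals[["R"]], P = vals[["P"]],
                S = vals[["S"]], b = NULL)
  } else {
    if (is.null(b)) {
      stop("supply either `b` or all four of T, R, P, S", call. = FALSE)
    }
    b <- as.numeric(b)
    if (!is.finite(b) || length(b) != 1L || b <= 0 || b >= 1) {
      stop("`b` must be a single value strictly inside (0, 1)",
           call. = FALSE)
    }
    out <- list(T = 1 + b, R = 1, P = b, S = 0, b = b)
    check_pd_ranking(out$T, out$R, out$P, out$S)
  }
  structure(out, class = "game_params")
}

check_pd_ranking <- function(T, R, P, S) {
  if (!(T > R && R > P && P > S)) {
    stop("payoffs must satisfy the Prisoner's Dilemma ranking T > R > P > S",
         call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("payoffs must satisfy 2R > T + S", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Prisoner's Dilemma game\n")
  if (!is.null(x$b)) cat(sprintf("  one-parameter form, b = %g\n", x$b))
  cat(sprintf("  T = %g, R = %g, P = %g, S = %g\n", x$T, x$R, x$P, x$S))
  invisible(x)
}

#' Build the 2x2 payoff matrix of a game
#'
#' Rows index the focal player's strategy, columns the co-player's strategy,
#' in the order (C, D); the row player receives the entry.
#'
#' @param params A [game_params()] object.
#' @return A 2x2 numeric matrix with dimnames `c("C", "D")`.
#' @examples
#' build_payoff_matrix(game_params(b = 0.5))
#' @export
build_payoff_matrix <- function(params) {
  if (!inherits(params, "game_params")) params <- do.call(game_params, as.list(params))
  m <- matrix(c(params$R, params$T, params$S, params$P), nrow = 2,
              dimnames = list(c("C", "D"), c("C", "D")))
  m
}

#' Accumulated payoff of one player
#'
#' The payoff of a player is accumulated (summed, not averaged) over one
#' round of the game with each of its current neighbors. Isolated players
#' earn 0.
#'
#' @param state A `popstate` object (see [init_regular_graph()]).
#' @param node Node id (1-based).
#' @param matrix A 2x2 payoff matrix from [build_payoff_matrix()].
#' @return The accumulated payoff, a single number.
#' @export
node_payoff <- function(state, node, matrix) {
  stopifnot(inherits(state, "popstate"))
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > state$N) {
    stop("unknown node id", call. = FALSE)
  }
  e <- state$edges
  nbrs <- c(e[e[, 1] == node, 2], e[e[, 2] == node, 1])
  if (length(nbrs) == 0L) return(0)
  s <- state$strategies
  sum(matrix[s[node], s[nbrs]])
}
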