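#' Population state: players on a graph with a fixed number of links
#'
#' A `popstate` bundles `N` players, their strategies (a character vector
#' over `"C"`/`"D"`), and an edge set of exactly `L` unordered links (an
#' `L x 2` integer matrix of 1-based node ids, each row sorted). The number
#' of links is conserved by every dynamical move in the package. Rewiring
#' may isolate nodes (degree 0); isolated players earn payoff 0.
#'
#' @name popstate
NULL

new_popstate <- function(N, strategies, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- t(apply(edges, 1, sort))
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (anyDuplicated(edges)) stop("duplicate edges are not allowed", call. = FALSE)
  structure(list(N = as.integer(N), strategies = strategies,
                 edges = edges, L = nrow(edges)),
            class = "popstate")
}

#' @export
print.popstate <- function(x, ...) {
  cat(sprintf("Population: N = %d players, L = %d links (mean degree %.2f)\n",
              x$N, x$L, 2 * x$L / x$N))
  if (!is.null(x$strategies)) {
    cat(sprintf("  cooperators: %d (x = %.3f)\n",
                sum(x$strategies == "C"), mean(x$strategies == "C")))
  }
  invisible(x)
}

#' Initialize a regular graph of players
#'
#' Builds the initial population structure: every player sits on a vertex
#' of a simple k-regular graph, so `L = N*k/2`. Strategies are unset until
#' [assign_strategies()] is called. Uses the current R random number
#' generator (seed with `set.seed()` for reproducibility).
#'
#' @param N Number of players.
#' @param k Degree of every node; `N*k` must be even and `k < N`.
#' @param topology `"random-regular"` (default; uniformish simple k-regular
#'   graph) or `"ring-lattice"` (each node linked to its k/2 nearest
#'   neighbors on each side; requires even `k`).
#' @return A `popstate` with strategies set to `NA`.
#' @examples
#' set.seed(1)
#' st <- init_regular_graph(20, 4)
#' @export
init_regular_graph <- function(N, k,
                               topology = c("random-regular", "ring-lattice")) {
  topology <- match.arg(topology)
  N <- as.integer(N); k <- as.integer(k)
  if (k < 2L) stop("degree k must be at least 2", call. = FALSE)
  if (k >= N) stop("degree k must be smaller than N", call. = FALSE)
  if ((N * k) %% 2L != 0L) stop("N*k must be even for a k-regular graph",
                                call. = FALSE)
  if (N < 10L * k) {
    warning("N < 10*k: the analytic link-type approximation assumes N >> k",
            call. = FALSE)
  }
  g <- switch(topology,
    "random-regular" = igraph::sample_k_regular(N, k),
    "ring-lattice" = {
      if (k %% 2L != 0L) stop("ring-lattice requires even k", call. = FALSE)
      igraph::make_lattice(length = N, dim = 1, nei = k %/% 2L,
                           periodic = TRUE)
    })
  edges <- igraph::as_edgelist(g, names = FALSE)
  new_popstate(N, rep(NA_character_, N), edges)
}

#' Assign initial strategies to the population
#'
#' @param state A `popstate`.
#' @param coop_fraction Initial cooperator fraction in `[0, 1]`.
#' @param mode `"exact-count"` places exactly `round(N * coop_fraction)`
#'   cooperators at uniformly random nodes; `"iid"` makes each node a
#'   cooperator independently with that probability.
#' @return The `popstate` with strategies filled in.
#' @export
assign_strategies <- function(state, coop_fraction,
                              mode = c("exact-count", "iid")) {
  stopifnot(inherits(state, "popstate"))
  mode <- match.arg(mode)
  x0 <- as.numeric(coop_fraction)
  if (!is.finite(x0) || x0 < 0 || x0 > 1) {
    stop("`coop_fraction` must lie in [0, 1]", call. = FALSE)
  }
  s <- rep("D", state$N)
  if (mode == "exact-count") {
    nC <- round(state$N * x0)
    if (nC > 0) s[sample.int(state$N, nC)] <- "C"
  } else {
    s[stats::runif(state$N) < x0] <- "C"
  }
  state$strategies <- s
  state
}

#' Link-breaking probabilities
#'
#' The triple (k_CC, k_CD, k_DD) of probabilities that a randomly selected
#' link of each type breaks during a linking event. Each must lie in
#' `[0, 1]`; the analytic stationary distribution additionally requires all
#' three to be strictly positive (irreducibility of the link-type chain).
#'
#' @param k_cc,k_cd,k_dd Breaking probabilities for CC, CD and DD links.
#' @return An object of class `link_break_probs`.
#' @examples
#' link_break_probs(0.2, 0.8, 0.4)
#' @export
link_break_probs <- function(k_cc, k_cd, k_dd) {
  k <- c(k_cc = as.numeric(k_cc), k_cd = as.numeric(k_cd),
         k_dd = as.numeric(k_dd))
  if (any(!is.finite(k)) || any(k < 0) || any(k > 1)) {
    stop("all breaking probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(k), class = "link_break_probs")
}

as_link_break_probs <- function(k) {
  if (inherits(k, "link_break_probs")) return(k)
  k <- unlist(k)
  if (length(k) != 3L) stop("expected three breaking probabilities",
                            call. = FALSE)
  link_break_probs(k[[1]], k[[2]], k[[3]])
}

#' @export
print.link_break_probs <- function(x, ...) {
  cat(sprintf("Link-breaking probabilities: k_CC = %g, k_CD = %g, k_DD = %g\n",
              x$k_cc, x$k_cd, x$k_dd))
  invisible(x)
}

#' Classify a link by the strategies of its endpoints
#'
#' @param state A `popstate` with strategies assigned.
#' @param edge Length-2 vector of node ids; order is irrelevant.
#' @return One of `"CC"`, `"CD"`, `"DD"`.
#' @export
classify_link <- function(state, edge) {
  stopifnot(inherits(state, "popstate"))
  edge <- sort(as.integer(edge))
  found <- any(state$edges[, 1] == edge[1] & state$edges[, 2] == edge[2])
  if (!found) stop("edge not present in the network", call. = FALSE)
  s <- sort(state$strategies[edge])
  paste(s, collapse = "")
}

#' Count links of each type
#'
#' @param state A `popstate` with strategies assigned.
#' @return Named integer vector `c(n_cc, n_cd, n_dd)` summing to `L`.
#' @export
link_type_counts <- function(state) {
  stopifnot(inherits(state, "popstate"))
  isC <- state$strategies == "C"
  a <- isC[state$edges[, 1]]
  b <- isC[state$edges[, 2]]
  c(n_cc = sum(a & b), n_cd = sum(xor(a, b)), n_dd = sum(!a & !b))
}

#' One stochastic rewiring event
#'
#' Selects one link uniformly at random. With probability `1 - k_XY` (where
#' XY is the link's type) nothing happens. Otherwise the link breaks: one of
#' its two endpoints is picked with probability 1/2 and switches to a new
#' partner chosen uniformly among the nodes that are neither itself nor any
#' of its current neighbors (the old partner included). The total number of
#' links never changes. If the switching endpoint is already linked to every
#' other node, the break is cancelled and the link kept (impossible when
#' `N >> k`).
#'
#' This is the reference single-event implementation used for unit-level
#' reasoning; long simulations use the compiled core in [run_simulation()],
#' which applies the identical move.
#'
#' @param state A `popstate` with strategies assigned.
#' @param k_probs A [link_break_probs()] object.
#' @return A list with elements `state` (the updated `popstate`) and `event`
#'   (a list recording `edge`, `type`, `broken`, `cancelled`, `switching`,
#'   `new_partner`).
#' @export
rewire_event <- function(state, k_probs) {
  stopifnot(inherits(state, "popstate"))
  k_probs <- as_link_break_probs(k_probs)
  if (state$L < 1L) stop("no links to rewire", call. = FALSE)
  ei <- sample.int(state$L, 1L)
  edge <- state$edges[ei, ]
  type <- paste(sort(state$strategies[edge]), collapse = "")
  kxy <- switch(type, CC = k_probs$k_cc, CD = k_probs$k_cd, DD = k_probs$k_dd)
  event <- list(edge = edge, type = type, broken = FALSE, cancelled = FALSE,
                switching = NA_integer_, new_partner = NA_integer_)
  if (stats::runif(1) >= kxy) {
    return(list(state = state, event = event))
  }
  keeper <- edge[sample.int(2L, 1L)]
  e <- state$edges
  nbrs <- c(e[e[, 1] == keeper, 2], e[e[, 2] == keeper, 1])
  eligible <- setdiff(seq_len(state$N), c(keeper, nbrs))
  if (length(eligible) == 0L) {
    event$cancelled <- TRUE
    return(list(state = state, event = event))
  }
  new_partner <- eligible[sample.int(length(eligible), 1L)]
  e[ei, ] <- sort(c(keeper, new_partner))
  state$edges <- e
  event$broken <- TRUE
  event$switching <- keeper
  event$new_partner <- new_partner
  list(state = state, event = event)
}
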