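# Small fixtures and independent oracles shared across the suite.

# Build a popstate directly from parts (bypasses the graph generators).
make_state <- function(strategies, edges) {
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  linkdyn:::new_popstate(length(strategies), strategies, edges)
}

# Random simple graph state: N nodes, L edges sampled without replacement
# from all pairs, iid strategies.
random_state <- function(N, L, coop_prob = 0.5) {
  pairs <- t(utils::combn(N, 2))
  pick <- sample.int(nrow(pairs), L)
  make_state(ifelse(stats::runif(N) < coop_prob, "C", "D"), pairs[pick, ])
}

# Brute-force accumulated payoff: enumerate every edge incident to `node`
# and add the payoff of one game round. Independent of node_payoff().
payoff_by_edge_enumeration <- function(state, node, m) {
  total <- 0
  for (i in seq_len(state$L)) {
    e <- state$edges[i, ]
    if (node %in% e) {
      other <- setdiff(e, node)
      total <- total + m[state$strategies[node], state$strategies[other]]
    }
  }
  total
}

# Degree vector from the edge matrix.
degrees <- function(state) {
  tabulate(c(state$edges[, 1], state$edges[, 2]), nbins = state$N)
}

assert_simple <- function(state) {
  e <- state$edges
  expect_true(all(e[, 1] != e[, 2]))
  expect_equal(anyDuplicated(e), 0L)
  expect_identical(nrow(e), state$L)
}

ref_game <- function() game_params(b = 0.5)
ref_k <- function() link_break_probs(0.2, 0.8, 0.4)
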