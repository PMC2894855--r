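test_that("configuration validation names the offending setting", {
  expect_error(simulation_config(N = 99, degree = 5), "even")
  expect_error(simulation_config(W = 1.5), "`W`")
  expect_error(simulation_config(x0 = -0.1), "`x0`")
  expect_error(simulation_config(beta = -1), "`beta`")
  expect_error(simulation_config(generations = 100, transient = 90,
                                 window = 20), "transient")
})

test_that("elementary step dispatches by W", {
  set.seed(41)
  st <- assign_strategies(suppressWarnings(init_regular_graph(30, 4)), 0.5)
  cfg <- simulation_config(N = 30, degree = 4, W = 0, generations = 10,
                           transient = 0, window = 10, runs = 1)
  # W = 0: every event is a linking event; strategies never change
  for (i in 1:50) {
    out <- step(st, cfg)
    expect_equal(out$event$kind, "linking")
    expect_identical(out$state$strategies, st$strategies)
    st <- out$state
  }
  # W = 1: every event is a strategy event; the graph never changes
  cfg$W <- 1
  for (i in 1:50) {
    out <- step(st, cfg)
    expect_equal(out$event$kind, "strategy")
    expect_identical(out$state$edges, st$edges)
    st <- out$state
  }
})

test_that("event mix follows W binomially", {
  # beta = 0 and few generations: neutral drift, far from absorption, so
  # every one of the generations * N elementary events is counted
  cfg <- simulation_config(N = 100, degree = 10, W = 0.5, beta = 0,
                           generations = 100, transient = 0, window = 100,
                           runs = 1, seed = 5)
  res <- run_simulation(cfg)
  n_events <- 100 * 100
  n_strategy <- res$counters$strategy_events
  expect_equal(n_strategy + res$counters$linking_events, n_events)
  expect_lt(abs(n_strategy / n_events - 0.5), 3 * sqrt(0.25 / n_events))
})

test_that("runs are deterministic given (config, seed) and respect absorption", {
  cfg <- simulation_config(N = 50, degree = 4, generations = 500,
                           transient = 200, window = 300, runs = 3, seed = 99)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$final_coop, r2$final_coop)
  expect_identical(r1$counters, r2$counters)
  expect_identical(lapply(r1$final_states, `[[`, "edges"),
                   lapply(r2$final_states, `[[`, "edges"))

  # absorbing starts: exact 0/1 forever, no strategy flips possible
  for (x0 in c(0, 1)) {
    cfg0 <- simulation_config(N = 50, degree = 4, x0 = x0, generations = 50,
                              transient = 0, window = 50, runs = 2, seed = 3)
    r <- run_simulation(cfg0)
    expect_true(all(r$x == x0))
    expect_equal(r$final_coop, rep(x0, 2))
    expect_equal(r$counters$flips, 0)
  }
})

test_that("W = 0 conserves cooperation and converges to the analytic pi", {
  cfg <- simulation_config(N = 200, degree = 10, W = 0, x0 = 0.5,
                           generations = 800, transient = 400, window = 400,
                           runs = 2, seed = 8)
  res <- run_simulation(cfg, check = TRUE)
  expect_true(all(res$x == 0.5))            # cooperation level frozen
  p <- stationary_distribution(cfg$k, 0.5)$pi
  emp <- sapply(res$link_fractions, function(m) mean(m[401:800, ]))
  expect_lt(max(abs(emp - p)), 0.03)
  # link-type fractions always sum to one
  tot <- res$link_fractions$f_cc + res$link_fractions$f_cd +
    res$link_fractions$f_dd
  expect_equal(max(abs(tot - 1)), 0)
})

test_that("structural invariants hold through full coevolution runs", {
  # check = TRUE makes the compiled core assert simplicity, constant link
  # count, degree sums and link-type bookkeeping after every event
  cfg <- simulation_config(N = 100, degree = 8, W = 0.2, beta = 5,
                           generations = 300, transient = 100, window = 100,
                           runs = 2, seed = 44)
  res <- run_simulation(cfg, check = TRUE)
  for (st in res$final_states) {
    expect_equal(st$L, 100L * 8L / 2L)
    expect_true(all(st$edges[, 1] != st$edges[, 2]))
    expect_equal(anyDuplicated(st$edges), 0L)
    expect_equal(sum(tabulate(st$edges, nbins = 100)), 2 * st$L)
  }
  expect_true(all(res$x >= 0 & res$x <= 1))
})

test_that("basin curve rises with x0 and brackets the analytic threshold", {
  cfg <- simulation_config(N = 100, degree = 10, W = 0.01, beta = 10,
                           generations = 3000, transient = 1500,
                           window = 1000, runs = 6, seed = 21)
  curve <- final_cooperation_curve(cfg, x0_values = c(0.1, 0.5, 0.9))
  expect_equal(attr(curve, "x_star"), 2 / 7, tolerance = 1e-12)
  # deep in the defector basin vs deep in the cooperator basin
  expect_lt(curve$mean_final[1], 0.3)
  expect_gt(curve$mean_final[3], 0.7)
  expect_true(all(diff(curve$mean_final) >= 0))
})

test_that("phase sweep labels cells by the analytic rule", {
  cfg <- simulation_config(N = 100, degree = 10, W = 0.01, beta = 10,
                           generations = 2000, transient = 500, window = 1000,
                           runs = 2, seed = 77)
  # grid values chosen off the exact rule boundary k_cd = 1.5 * k_cc, where
  # the verdict would hinge on floating-point rounding
  grid <- sweep_phase_diagram(cfg, axes = c("k_cc", "k_cd"),
                              values1 = c(0.1, 0.6), values2 = c(0.2, 0.85),
                              runs = 2)
  expect_equal(nrow(grid), 4L)
  expect_equal(grid$stable, grid$g > 0.5)
  expect_true(all(grid$mean_final >= 0 & grid$mean_final <= 1))
  expect_error(sweep_phase_diagram(cfg, axes = c("k_cc", "k_cc"),
                                   values1 = 1, values2 = 1), "distinct")
  expect_error(sweep_phase_diagram(cfg, axes = c("k_cc", "bogus"),
                                   values1 = 1, values2 = 1), "axes")
})
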