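#' Simulation configuration
#'
#' Describes one coevolution experiment. A generation is `N` elementary
#' events (so each agent gets on average `W` strategy-update opportunities
#' per generation); the final cooperation level of a run is the time average
#' of the cooperator fraction over the `window` generations following the
#' `transient`. All defaults are the package's desk-scale study conditions
#' (see the methods vignette).
#'
#' @param N Population size.
#' @param degree Mean (initial) degree; `N * degree` must be even.
#' @param game A [game_params()] object (default `game_params(b = 0.5)`).
#' @param k A [link_break_probs()] object (default `(0.2, 0.8, 0.4)`).
#' @param W Probability that an elementary event is a strategy update
#'   (otherwise a linking event). `W << 1` is the fast-linking regime in
#'   which the analytics are exact.
#' @param beta Selection intensity (default 10: strong selection).
#' @param x0 Initial cooperator fraction.
#' @param topology Initial graph: `"random-regular"` or `"ring-lattice"`.
#' @param strategy_mode `"exact-count"` or `"iid"` (see
#'   [assign_strategies()]).
#' @param generations Generations per run.
#' @param transient Generations discarded before averaging.
#' @param window Averaging window (generations); `transient + window`
#'   must not exceed `generations`.
#' @param runs Independent replicate runs.
#' @param seed Integer seed; fully determines every event of every run.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(N = 100, degree = 10,
                              game = game_params(b = 0.5),
                              k = link_break_probs(0.2, 0.8, 0.4),
                              W = 0.01, beta = 10, x0 = 0.5,
                              topology = c("random-regular", "ring-lattice"),
                              strategy_mode = c("exact-count", "iid"),
                              generations = 10000, transient = 5000,
                              window = 1000, runs = 20, seed = 1L) {
  topology <- match.arg(topology)
  strategy_mode <- match.arg(strategy_mode)
  cfg <- list(N = as.integer(N), degree = as.integer(degree), game = game,
              k = as_link_break_probs(k), W = as.numeric(W),
              beta = as.numeric(beta), x0 = as.numeric(x0),
              topology = topology, strategy_mode = strategy_mode,
              generations = as.integer(generations),
              transient = as.integer(transient), window = as.integer(window),
              runs = as.integer(runs), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  check_range <- function(name, value, lo, hi) {
    if (!is.finite(value) || value < lo || value > hi) {
      stop(sprintf("`%s` must lie in [%g, %g] (got %g)", name, lo, hi, value),
           call. = FALSE)
    }
  }
  if (cfg$N < 3L) stop("`N` must be at least 3", call. = FALSE)
  if ((cfg$N * cfg$degree) %% 2L != 0L) {
    stop("`N * degree` must be even", call. = FALSE)
  }
  if (cfg$degree >= cfg$N) stop("`degree` must be smaller than `N`",
                                call. = FALSE)
  check_range("W", cfg$W, 0, 1)
  check_range("x0", cfg$x0, 0, 1)
  if (cfg$beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (cfg$generations < 1L) stop("`generations` must be positive", call. = FALSE)
  if (cfg$transient < 0L || cfg$window < 1L ||
      cfg$transient + cfg$window > cfg$generations) {
    stop("`transient` + `window` must not exceed `generations`", call. = FALSE)
  }
  if (cfg$runs < 1L) stop("`runs` must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Coevolution config: N = %d, degree = %d, W = %g, ",
                     "beta = %g, x0 = %g\n"),
              x$N, x$degree, x$W, x$beta, x$x0))
  cat(sprintf("  k = (%g, %g, %g); %d generations x %d runs; seed %d\n",
              x$k$k_cc, x$k$k_cd, x$k$k_dd, x$generations, x$runs, x$seed))
  invisible(x)
}

#' One elementary coevolution step
#'
#' With probability `W` performs a strategy (imitation) event, otherwise a
#' linking (rewiring) event — exactly one elementary event. With `W = 0`
#' only the network changes and the cooperation level stays constant; with
#' `W = 1` the graph never changes and the model reduces to the game on a
#' static graph.
#'
#' Reference implementation in R; [run_simulation()] applies the identical
#' step in compiled code.
#'
#' @param state A `popstate`.
#' @param config A `sim_config` (only `game`, `k`, `W`, `beta` are used).
#' @return A list with `state` and `event` (the underlying event record,
#'   plus `kind` = `"strategy"` or `"linking"`).
#' @export
step <- function(state, config) {
  if (stats::runif(1) < config$W) {
    out <- imitation_event(state, build_payoff_matrix(config$game),
                           config$beta)
    out$event$kind <- "strategy"
  } else {
    out <- rewire_event(state, config$k)
    out$event$kind <- "linking"
  }
  out
}

#' Run a coevolution experiment
#'
#' Executes `runs` independent replicates of `generations * N` elementary
#' events each, recording the cooperator fraction and the link-type
#' fractions once per generation. The final cooperation level of a run is
#' the mean cooperator fraction over generations
#' `transient + 1, ..., transient + window`. Because there is no mutation,
#' full defection and full cooperation are absorbing whenever `W > 0`; runs
#' that hit a boundary stop early and the recorded series is padded with
#' the absorbed value (an exact shortcut, not an approximation).
#'
#' The experiment is fully reproducible: `config$seed` determines every
#' replicate (per-replicate sub-seeds are drawn once from it).
#'
#' @param config A [simulation_config()].
#' @param check Assert structural invariants (link count, simplicity,
#'   degree sum, link-type bookkeeping) after every event — used by the test
#'   suite; slows the run.
#' @return An object of class `sim_result`: list with
#'   * `x`: generations x runs matrix of cooperator fractions,
#'   * `link_fractions`: list of three generations x runs matrices
#'     (`f_cc`, `f_cd`, `f_dd`),
#'   * `final_coop`: per-run final cooperation levels,
#'   * `mean_final`, `sd_final`: across-run summary,
#'   * `counters`: summed event counters,
#'   * `absorbed_gen`: per-run absorption generation (NA if never),
#'   * `final_states`: per-run final `popstate`s,
#'   * `config`: the configuration echo.
#' @export
run_simulation <- function(config, check = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$runs)
  G <- config$generations
  x_mat <- matrix(NA_real_, G, config$runs)
  fcc <- fcd <- fdd <- matrix(NA_real_, G, config$runs)
  final_coop <- numeric(config$runs)
  absorbed <- rep(NA_integer_, config$runs)
  counters <- NULL
  final_states <- vector("list", config$runs)
  pay <- build_payoff_matrix(config$game)
  kv <- c(config$k$k_cc, config$k$k_cd, config$k$k_dd)
  avg_idx <- (config$transient + 1L):(config$transient + config$window)
  for (r in seq_len(config$runs)) {
    set.seed(sub_seeds[r])
    st <- init_regular_graph(config$N, config$degree, config$topology)
    st <- assign_strategies(st, config$x0, config$strategy_mode)
    res <- run_core(as.integer(st$strategies == "C"), st$edges - 1L, pay,
                    kv, config$W, config$beta, G, check, TRUE)
    x_mat[, r] <- res$x
    fcc[, r] <- res$f_cc; fcd[, r] <- res$f_cd; fdd[, r] <- res$f_dd
    final_coop[r] <- mean(res$x[avg_idx])
    absorbed[r] <- res$absorbed_gen
    counters <- if (is.null(counters)) res$counters else
      Map(`+`, counters, res$counters)
    final_states[[r]] <- new_popstate(
      config$N, ifelse(res$strategies == 1L, "C", "D"), res$edges + 1L)
  }
  structure(list(
    x = x_mat,
    link_fractions = list(f_cc = fcc, f_cd = fcd, f_dd = fdd),
    final_coop = final_coop,
    mean_final = mean(final_coop),
    sd_final = stats::sd(final_coop),
    counters = counters,
    absorbed_gen = absorbed,
    final_states = final_states,
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Coevolution result: %d runs of %d generations (N = %d)\n",
              cfg$runs, cfg$generations, cfg$N))
  cat(sprintf("  mean final cooperation: %.3f (sd %.3f)\n",
              x$mean_final, if (is.na(x$sd_final)) 0 else x$sd_final))
  cat(sprintf("  events: %d strategy flips, %d rewires (%d cancelled)\n",
              as.integer(x$counters$flips), as.integer(x$counters$breaks),
              as.integer(x$counters$cancelled_breaks)))
  invisible(x)
}

#' Final cooperation as a function of the initial cooperator fraction
#'
#' Runs the basin-of-attraction protocol: for each initial fraction `x0`
#' in `x0_values`, `runs` independent replicates are simulated and the mean
#' final cooperation recorded. Under strong selection and fast linking
#' (`beta` large, `W` small) the empirical curve switches from ~0 to ~1
#' near the analytic unstable equilibrium `x*`, which is attached for
#' overlay.
#'
#' @param config Base [simulation_config()]; its `x0` and `runs` are
#'   overridden per point.
#' @param x0_values Initial cooperator fractions to scan.
#' @param runs Replicates per point (default `config$runs`).
#' @return A data.frame with columns `x0`, `mean_final`, `sd_final`, `runs`,
#'   and attribute `x_star` (the analytic threshold, `NA` if absent).
#' @export
final_cooperation_curve <- function(config, x0_values = seq(0.05, 0.95, 0.05),
                                    runs = config$runs) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  point_seeds <- sample.int(.Machine$integer.max, length(x0_values))
  rows <- lapply(seq_along(x0_values), function(i) {
    cfg <- config
    cfg$x0 <- x0_values[i]
    cfg$runs <- as.integer(runs)
    cfg$seed <- point_seeds[i]
    res <- run_simulation(cfg)
    data.frame(x0 = x0_values[i], mean_final = res$mean_final,
               sd_final = res$sd_final, runs = runs)
  })
  out <- do.call(rbind, rows)
  attr(out, "x_star") <- interior_equilibrium(config$game, config$k)
  out
}

#' Phase diagram over two parameters
#'
#' Runs the phase-diagram protocol: mean final cooperation on a grid over
#' two chosen parameters, with everything else fixed by `config`. The
#' analytic stability classification (`g > b`, evaluated per cell) is
#' attached so the rule boundary `k_CD = (1 + b) k_CC` can be overlaid.
#'
#' @param config Base [simulation_config()].
#' @param axes Character vector of two parameter names among
#'   `"k_cc"`, `"k_cd"`, `"k_dd"`, `"b"`, `"beta"`, `"W"`.
#' @param values1,values2 Grid values for the two axes.
#' @param runs Replicates per cell (default `config$runs`).
#' @return A data.frame with one row per cell: the two axis columns,
#'   `mean_final`, `sd_final`, `g`, `stable`.
#' @export
sweep_phase_diagram <- function(config, axes = c("k_cc", "k_cd"),
                                values1, values2, runs = config$runs) {
  stopifnot(inherits(config, "sim_config"))
  allowed <- c("k_cc", "k_cd", "k_dd", "b", "beta", "W")
  if (length(axes) != 2L || !all(axes %in% allowed) || axes[1] == axes[2]) {
    stop(sprintf("`axes` must be two distinct names among %s",
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  grid <- expand.grid(v1 = values1, v2 = values2, KEEP.OUT.ATTRS = FALSE)
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  set_param <- function(cfg, name, value) {
    if (name == "b") {
      cfg$game <- game_params(b = value)
    } else if (name %in% c("k_cc", "k_cd", "k_dd")) {
      kk <- cfg$k; kk[[name]] <- value
      cfg$k <- link_break_probs(kk$k_cc, kk$k_cd, kk$k_dd)
    } else {
      cfg[[name]] <- value
    }
    cfg
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg <- set_param(cfg, axes[1], grid$v1[i])
    cfg <- set_param(cfg, axes[2], grid$v2[i])
    cfg$runs <- as.integer(runs)
    cfg$seed <- cell_seeds[i]
    validate_config(cfg)
    res <- run_simulation(cfg)
    b_eff <- if (!is.null(cfg$game$b)) cfg$game$b else NA_real_
    data.frame(grid$v1[i], grid$v2[i], mean_final = res$mean_final,
               sd_final = res$sd_final,
               g = fragility_index(cfg$k),
               stable = cooperation_stable(cfg$game, cfg$k),
               b = b_eff)
  })
  out <- do.call(rbind, rows)
  names(out)[1:2] <- axes
  out
}
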