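#' Pairwise-comparison (Fermi) imitation probability
#'
#' The probability that a focal player with payoff `payoff_i` adopts the
#' strategy of a comparison player with payoff `payoff_j`:
#' `1 / (1 + exp(-beta * (payoff_j - payoff_i)))`. The selection intensity
#' `beta >= 0` interpolates between random imitation (`beta = 0`, probability
#' 1/2 regardless of payoffs) and deterministic imitation of the better
#' performer (`beta -> Inf`). Numerically stable for arbitrarily large
#' `|beta * (payoff_j - payoff_i)|`.
#'
#' @param payoff_i Focal player's accumulated payoff (vectorized).
#' @param payoff_j Comparison player's accumulated payoff (vectorized).
#' @param beta Selection intensity, `>= 0`.
#' @return Imitation probability in `[0, 1]`.
#' @examples
#' fermi_probability(2, 2, 1)       # 0.5
#' fermi_probability(0, 10, 10)     # ~1
#' @export
fermi_probability <- function(payoff_i, payoff_j, beta) {
  if (any(beta < 0)) stop("`beta` must be >= 0", call. = FALSE)
  z <- beta * (payoff_j - payoff_i)
  # evaluate on the side that cannot overflow
  p <- ifelse(z >= 0,
              1 / (1 + exp(-z)),
              exp(z) / (1 + exp(z)))
  # exp(z) underflows to 0 for z << 0, giving exactly 0; z >> 0 gives 1
  p
}

#' One stochastic imitation event
#'
#' Picks a focal player uniformly from the population, then one of its
#' current neighbors uniformly. Both accumulated payoffs are computed from
#' the current graph at the moment of the event (rewiring continually
#' changes neighborhoods, so payoffs are never cached). The focal player
#' adopts the neighbor's strategy with the Fermi probability; at most one
#' strategy changes per event. A focal player without neighbors cannot
#' imitate anyone and the state is unchanged.
#'
#' Reference single-event implementation; long simulations use the compiled
#' core in [run_simulation()], which applies the identical move.
#'
#' @param state A `popstate` with strategies assigned.
#' @param matrix 2x2 payoff matrix from [build_payoff_matrix()].
#' @param beta Selection intensity.
#' @return A list with `state` and `event` (list with `focal`, `neighbor`,
#'   `flipped`, `isolated`).
#' @export
imitation_event <- function(state, matrix, beta) {
  stopifnot(inherits(state, "popstate"))
  focal <- sample.int(state$N, 1L)
  e <- state$edges
  nbrs <- c(e[e[, 1] == focal, 2], e[e[, 2] == focal, 1])
  event <- list(focal = focal, neighbor = NA_integer_, flipped = FALSE,
                isolated = length(nbrs) == 0L)
  if (event$isolated) return(list(state = state, event = event))
  j <- nbrs[sample.int(length(nbrs), 1L)]
  event$neighbor <- j
  if (state$strategies[focal] != state$strategies[j]) {
    p_f <- node_payoff(state, focal, matrix)
    p_j <- node_payoff(state, j, matrix)
    if (stats::runif(1) < fermi_probability(p_f, p_j, beta)) {
      state$strategies[focal] <- state$strategies[j]
      event$flipped <- TRUE
    }
  }
  list(state = state, event = event)
}

#' Replicator right-hand side under fast linking
#'
#' The deterministic gradient `dx/dt = x (1 - x) (f_C(x) - f_D(x))` with the
#' stationary-link-weighted mean payoffs of [mean_payoffs()]. Shares its
#' equilibria (the boundaries and, when cooperation is stable, the interior
#' unstable root `x*`) with the pairwise-comparison mean-field dynamics of
#' [evolve_mean_field()].
#'
#' @param x Cooperator frequency in `[0, 1]`; vectorized.
#' @param game A [game_params()] object.
#' @param k A [link_break_probs()] object.
#' @return `dx/dt`, same length as `x`.
#' @export
replicator_rhs <- function(x, game, k) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  interior <- x > 0 & x < 1
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  if (any(interior)) {
    p <- mean_payoffs(x[interior], game, k, N = 100, L = 500)
    out[interior] <- x[interior] * (1 - x[interior]) * (p$f_c - p$f_d)
  }
  out
}

#' Mean-field evolution of the cooperator frequency
#'
#' Integrates the pairwise-comparison mean dynamics under time-scale
#' separation,
#' `dx/dt = x (1 - x) tanh(beta (f_C - f_D) / 2)`,
#' by a fixed-step explicit Euler(-Maruyama) scheme with post-step clipping
#' to `[0, 1]`. With `noise = TRUE` an additive Gaussian term of amplitude
#' `noise_amp * sqrt(2 x (1 - x) / N)` per unit time is added (finite-size
#' demographic noise; it vanishes as `N^{-1/2}`, recovering the
#' deterministic flow for large populations). The deterministic flow is
#' bistable when an interior equilibrium exists: trajectories converge to 0
#' below `x*` and to 1 above it.
#'
#' @param x0 Initial cooperator frequency (vectorized: one trajectory per
#'   element).
#' @param game A [game_params()] object.
#' @param k A [link_break_probs()] object.
#' @param beta Selection intensity.
#' @param N Population size controlling the noise amplitude.
#' @param horizon Total integration time.
#' @param step Time step (default 0.01).
#' @param noise Add the finite-size noise term?
#' @param noise_amp Constant factor on the noise amplitude (default 1).
#' @return A data.frame with column `t` and one column `x` per trajectory
#'   (named `x` for a single trajectory, `x1`, `x2`, ... otherwise).
#' @examples
#' game <- game_params(b = 0.5); k <- link_break_probs(0.2, 0.8, 0.4)
#' tr <- evolve_mean_field(c(0.2, 0.4), game, k, beta = 10, N = 100,
#'                         horizon = 30)
#' @export
evolve_mean_field <- function(x0, game, k, beta, N, horizon, step = 0.01,
                              noise = FALSE, noise_amp = 1) {
  x0 <- as.numeric(x0)
  if (any(!is.finite(x0)) || any(x0 < 0) || any(x0 > 1)) {
    stop("`x0` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(step) || step <= 0) stop("`step` must be positive", call. = FALSE)
  if (!is.finite(horizon) || horizon <= 0) stop("`horizon` must be positive",
                                                call. = FALSE)
  n_steps <- ceiling(horizon / step)
  m <- length(x0)
  traj <- matrix(NA_real_, n_steps + 1L, m)
  traj[1L, ] <- x0
  x <- x0
  for (i in seq_len(n_steps)) {
    dx <- drift_mean_field(x, game, k, beta) * step
    if (noise) {
      dx <- dx + noise_amp * sqrt(pmax(2 * x * (1 - x) / N, 0)) *
        sqrt(step) * stats::rnorm(m)
    }
    x <- pmin(pmax(x + dx, 0), 1)
    traj[i + 1L, ] <- x
  }
  out <- data.frame(t = seq(0, by = step, length.out = n_steps + 1L))
  cols <- if (m == 1L) "x" else paste0("x", seq_len(m))
  out[cols] <- as.data.frame(traj)
  out
}

# tanh-form drift of the pairwise-comparison mean dynamics; same roots as
# replicator_rhs since tanh is odd and vanishes only at 0.
drift_mean_field <- function(x, game, k, beta) {
  out <- numeric(length(x))
  interior <- x > 0 & x < 1
  if (any(interior)) {
    p <- mean_payoffs(x[interior], game, k, N = 100, L = 500)
    out[interior] <- x[interior] * (1 - x[interior]) *
      tanh(beta * (p$f_c - p$f_d) / 2)
  }
  out
}
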