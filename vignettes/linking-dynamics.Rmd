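---
title: "Linking dynamics and the evolution of cooperation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking dynamics and the evolution of cooperation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkdyn)
```

## The model

`linkdyn` implements a coevolutionary model in which both the strategies of
players and the social network connecting them evolve stochastically. `N`
players occupy the vertices of a graph with a *constant* number of links
`L = N k̄ / 2`; each plays the Prisoner's Dilemma with all current
neighbors, and payoffs are accumulated (summed), not averaged.

The one-parameter Prisoner's Dilemma used throughout has payoffs

|            | C       | D   |
|------------|---------|-----|
| **C**      | R = 1   | S = 0 |
| **D**      | T = 1+b | P = b |

with `b ∈ (0, 1)` measuring how profitable unilateral defection is
(`b = T − R = P − S`). These entries satisfy the strict ranking
`T > R > P > S` and `2R > T + S` for every admissible `b`. This particular
one-parameter family was chosen over the common alternative
(`R = 1, S = −b, T = 1 + b, P = 0`) because it keeps the interior
equilibrium sensitive to the defector–defector breaking probability — the
structure the analysis below exhibits — whereas the alternative makes it
degenerate. Users who want a different Prisoner's Dilemma can pass explicit
`(T, R, P, S)` to `game_params()`.

Each elementary event is, with probability `W`, a **strategy update**:
a focal player `i` is drawn uniformly, one current neighbor `j` uniformly,
and `i` adopts `j`'s strategy with the pairwise-comparison (Fermi)
probability `1 / (1 + exp(−β (p_j − p_i)))`, where `p` are accumulated
payoffs recomputed from the current graph at the moment of the event.
Otherwise (probability `1 − W`) it is a **linking event**: a link is drawn
uniformly among the `L` links and breaks with probability `k_XY` determined
by the strategies of its endpoints (`XY ∈ {CC, CD, DD}`); on a break, one of
the two endpoints is picked with probability 1/2 and switches to a new
partner drawn uniformly among the nodes that are neither itself nor any of
its current neighbors. The link count `L` is conserved exactly; nodes may
become isolated, in which case they earn payoff 0 and skip imitation when
focal.

## The link-type Markov chain

Fix the cooperator frequency `x` (no strategy updates). Follow one link
through time, letting a broken link bequeath its identity to its
replacement. Its type then performs a Markov chain on `{CC, CD, DD}` whose
single-event transition probabilities follow from the event tree: the link
is selected with probability `1/L`; a selected link of type `XY` breaks with
probability `k_XY`; the switching endpoint keeps its own strategy, and its
new partner is a cooperator with probability `x`; from a `CD` link the C or
D side switches with probability 1/2 each. Direct `CC ↔ DD` moves are
impossible, so the chain is a three-state birth–death chain and its
stationary distribution follows from detailed balance:

```
pi_CC : pi_CD : pi_DD  =  x^2 / k_CC  :  2 x (1 - x) / k_CD  :  (1 - x)^2 / k_DD
```

normalized to sum one. It is independent of `L`, requires all `k_XY > 0`
(irreducibility), and reduces to the binomial pairing
`(x², 2x(1−x), (1−x)²)` when all breaking probabilities are equal — random
pairing is recovered when the dynamics is blind to link types.
`stationary_distribution()` evaluates the closed form; the test suite checks
it against the numerically computed left eigenvector of
`transition_matrix()` and against long frozen-strategy simulations.

The closed form treats the new partner as a uniform draw from the whole
population at frequency `x`. The simulator, by contrast, excludes the
switching node's current neighbors (no duplicate links). This gap vanishes
as `N ≫ k̄`; at `N = 200`, `k̄ = 10` it shows up as a systematic deviation
of up to about 0.01–0.02 in the most persistent link-type fraction, which
is why the package warns when `N < 10 k̄`.

## Mean payoffs, the transformed game, and the stability rule

When `W ≪ 1` the network reaches its stationary composition between
strategy updates (time-scale separation). The expected number of `XY` links
is then `L π_XY(x)`, and dividing the total payoff flowing to each strategy
by its head count gives the mean payoffs implemented in `mean_payoffs()`:

```
f_C = (2 L pi_CC R + L pi_CD S) / (N x)
f_D = (2 L pi_DD P + L pi_CD T) / (N (1 - x))
```

Substituting the closed-form `pi` shows that `f_C − f_D` is, up to a
positive factor, the replicator gradient of a **transformed game** whose
entries are the original entries divided by the breaking probability of the
link type that delivers them:

```
R' = R / k_CC,   S' = S / k_CD,   T' = T / k_CD,   P' = P / k_DD
```

Robust link types are effectively amplified. The Prisoner's Dilemma becomes
a coordination game exactly when `R' > T'`, i.e. when

```
g  =  k_CD / k_CC − 1  >  b
```

(`fragility_index()` and `cooperation_stable()`; ties are classified as not
stable). `g` measures how much more fragile mixed links are than
cooperator–cooperator links; when it exceeds the temptation `b`, full
cooperation is evolutionarily stable and an interior *unstable* equilibrium

```
x* = b / (b + (g − b) k_DD / k_CD)
```

appears (`interior_equilibrium()`): initial cooperator frequencies above
`x*` flow to full cooperation, those below to full defection, so `1 − x*`
is the basin of attraction of cooperation. Two monotonicity properties
follow and are asserted in the suite: `x*` decreases in `g` (more fragile
mixed links enlarge the basin) and, when the rule holds, decreases in
`k_DD` (fast defector–defector breakup also enlarges the basin), while the
stability *verdict* itself never depends on `k_DD`. All closed forms are
cross-checked at test time against an independent bisection root of
`f_C − f_D` and against the standard interior-root formula of the
transformed 2×2 game.

## Mean-field dynamics

`evolve_mean_field()` integrates the pairwise-comparison mean dynamics
`dx/dt = x(1−x) tanh(β (f_C − f_D)/2)` with an explicit fixed-step scheme
(default step 0.01) and post-step clipping to `[0, 1]`; this is adequate
because the drift is smooth and bounded on a compact interval and every
question asked of it concerns equilibria and basins, not trajectory
accuracy. The optional noise term has amplitude `sqrt(2 x (1 − x) / N)` per
unit time — the standard finite-population scaling, with the constant
exposed as `noise_amp` since only the `N^{-1/2}` decay is contractual.
`replicator_rhs()` is the plain replicator form; the two share equilibria
(an odd saturating function does not move roots), which is the property the
tests assert.

## Study conditions and defaults

The simulator's defaults are the package's desk-scale study conditions,
chosen once for statistical stability on a single CPU:

| Parameter | Default | Meaning |
|---|---|---|
| `N` | 100 | players |
| `degree` | 10 | initial (and mean) degree, `L = 500` |
| `b` | 0.5 | temptation advantage of defection |
| `k` | (0.2, 0.8, 0.4) | breaking probabilities (CC, CD, DD); `g = 3 > b` |
| `W` | 0.01 | strategy-update share of events (fast-linking regime) |
| `beta` | 10 | selection intensity (strong selection) |
| `generations` | 10⁴ | one generation = `N` elementary events |
| `transient`, `window` | 5×10³, 10³ | discard, then time-average window |
| `runs` | 20 | independent replicates |

The initial graph is a random regular graph by default (a ring lattice is
available); strategies are seeded either as an exact count or iid. Because
there is no mutation, full cooperation and full defection are absorbing for
`W > 0`; runs stop early at absorption and pad the recorded series, an
exact shortcut. One integer seed determines every event of every replicate.

What the generator emulates is the model itself — there is no external
data. What it does *not* emulate is anything beyond the model's idealized
world: payoff noise, heterogeneous update rules, mutation, or empirical
network topologies. Passing tests therefore validate the implementation
and the internal consistency of the analytics, not the model's fit to any
real social system.

## Known limitations

* **Finite-size gap of the link-type chain.** See above; the frozen-strategy
  agreement between simulation and closed form is verified at `N = 200`,
  `k̄ = 10` to within 0.02 per component, with the residual being the
  documented duplicate-exclusion bias, largest when one breaking
  probability is much smaller than the others.
* **The basin threshold of the stochastic model sits above `x*`.** The
  analytic `x*` equates *population-mean* payoffs. The simulator's
  imitation events, however, compare payoffs across a *link*: conditional
  on a mixed link, the defector side is systematically richer than the
  average defector (it certainly has one cooperator neighbor) and the
  cooperator side poorer than the average cooperator. Under strong
  selection this pair-level correlation shifts the empirical
  basin-of-attraction threshold above `x*` — at the desk-scale conditions
  (`N = 100`, `k̄ = 10`, `β = 10`, `W = 0.01`) the measured transition
  midpoint is near 0.45–0.5 against `x* ≈ 0.286`, and the shift persists at
  larger `N`, smaller `W` and weaker selection. The qualitative picture
  (sharp 0→1 transition, monotone in `x₀`, threshold between the analytic
  basin boundaries, cooperation concentrated on the `g > b` side of the
  phase diagram, accuracy degrading as `W → 1`) is reproduced and tested;
  the quantitative midpoint location is a pair-level effect outside the
  mean-field analytics, and degree-resolved (pair-approximation)
  corrections are out of the package's scope.
* **Boundary conventions.** `g = b` (equivalently `R' = T'`) is classified
  as not stable; `x = 0` and `x = 1` return point-mass link distributions
  as explicit limits; grids that place cells exactly on the rule boundary
  `k_CD = (1 + b) k_CC` are classified by floating-point rounding and are
  avoided in the shipped experiments.

## A worked example

```{r example}
game <- game_params(b = 0.5)
k <- link_break_probs(k_cc = 0.2, k_cd = 0.8, k_dd = 0.4)
analytic_summary(game, k)

cfg <- simulation_config(N = 100, degree = 10, game = game, k = k,
                         x0 = 0.6, generations = 2000, transient = 1000,
                         window = 500, runs = 5, seed = 11)
run_simulation(cfg)
```
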