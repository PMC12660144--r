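---
title: "Copy or collaborate: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy or collaborate: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skillscape)
```

## The model

A group of `n` agents searches for the highest-payoff cell of a `width` ×
`height` grid of candidate solutions. Each cell carries a payoff in [0, 1]
and an integer *skill* label in 1..`s`; each agent likewise carries one
skill label. An agent standing on a cell can always evaluate (and move to)
its own cell and the 8 Moore-adjacent cells, and additionally any cell
whose center lies within Euclidean distance `r` of its own and whose skill
label matches the agent's. Skills are the model's operationalization of
diverse perspectives: a cardiologist and a gastroenterologist shown the same
chart notice different things, so the set of "visible" next steps differs
by training even from the same vantage point.

Agents are linked by an unweighted, undirected network and use their ties in
one of two ways when it is their turn to update:

* **Copy** — the candidate set is the individual visible set plus the cells
  the agent's network neighbors currently occupy.
* **Collaborate** — the candidate set is the individual visible set plus
  every cell within `r` whose skill matches *any* neighbor's skill; the
  neighbors lend their perception, not their position.

The agent moves to the highest-payoff candidate only if it strictly beats
the payoff of its current cell; otherwise it stays. Time advances in
rounds: each round draws a fresh uniform permutation of the agents and
updates them sequentially, so later agents in the permutation see earlier
agents' new positions. Under the `constant_p` schedule each update
collaborates with probability `p` and copies otherwise; under the `phase`
schedule all updates collaborate for the first `k` rounds of a fixed
`total_rounds` horizon and copy afterwards. A `constant_p` run ends after
the first round in which nobody moves — and it must end, because any move
strictly increases one agent's payoff on a finite grid. Phase runs always
last exactly `total_rounds` rounds.

## Landscapes

Two generators define the problem difficulty:

* **Complex** (`generate_complex_landscape()`): a unimodal bivariate
  Gaussian *signal* of variance 3 (in squared cells) centered on a uniformly
  random cell, summed with fractal Perlin noise and min-max normalized to
  [0, 1]. The narrow signal makes the global peak a needle; the noise
  carpets the grid with local optima (several hundred per 100 × 100 grid at
  the defaults) that trap hill climbers.
* **Simple** (`generate_simple_landscape()`): a single broad Gaussian bump,
  strictly decreasing in distance from its peak — one optimum, no traps.

Normalizing every landscape to exactly [0, 1] puts independently generated
runs on a common payoff scale, which is what makes averaging outcomes over
hundreds of replicates meaningful.

### Noise parameters

The Perlin field is the sum of `octaves = 4` octaves with `persistence =
0.5` and `lacunarity = 2`, starting from a `base_period = 10` cell coarsest
octave, so the dominant noise features span several cells and the finest
octave adds roughness at just over cell scale. The summed field is rescaled
to [0, 1] and multiplied by `amplitude = 1`, making the noise and the
unit-height signal contribute comparably. These four numbers are exposed in
`noise_spec()` because no canonical values exist for this construction;
they were fixed once, on the grounds above, and the package's qualitative
claims should be read as statements about this parameterization.

### Two numerical subtleties

* A variance-3 Gaussian on a 100 × 100 grid underflows to *exactly* zero
  beyond distance ≈ 120, which is harmless under noise but fatal alone: a
  flat far field is wall-to-wall weak local optima, and agents stranded
  there can never move. The simple generator therefore uses a broad bump
  (`signal_sd = min(width, height) / 4` by default), keeping the gradient
  resolvable in double precision everywhere on the grid.
* A *local optimum* is defined weakly — no strictly greater payoff among the
  up-to-8 Moore neighbors — matching the movement rule's strict-improvement
  test, so "agent stuck" and "agent on a local optimum of its neighborhood"
  coincide exactly.

## Dynamics: determinism, ties, and the RNG contract

Every run is driven by one master seed, split up front into five substreams
(landscape, skill grid, network randomization, agent initialization,
dynamics), so a run is bit-reproducible and insensitive to what else the
session computed. Batches likewise derive all per-run seeds up front, which
makes run *i* independent of whether run *j* was executed.

The dynamics stream is consumed in a documented order — one permutation per
round; one uniform per agent update in `constant_p` mode (drawn even when
`p` is 0 or 1, so runs with different `p` are comparable under matched
seeds, and the edgeless baseline is *exactly* invariant to `p`); and one
draw to break a tie only when an improving move has two or more distinct
maximal cells. Ties are resolved uniformly over the tied cells *sorted by
linear index*, so the outcome does not depend on the order in which an
implementation happens to enumerate candidates; the test suite exploits
this by replaying whole trajectories against a naive double-loop reference
implementation and demanding bit-identical histories.

Agents may share a cell (copying could not converge otherwise), and an
agent's payoff sequence is non-decreasing by construction.

## The experiment harness

`run_batch()` replicates a configuration; `summarize_runs()` reduces final
or per-step states to max/mean/min payoff and the Gini coefficient with
standard errors across runs; `run_protocol()` wires these into four named
designs (time series with an individual baseline, a `p` sweep over path and
complete networks, a density sweep, and a collaborate-then-copy `k` sweep)
and writes a tidy CSV plus a JSON manifest. Default replication is 1000
runs per condition, the scale at which the sweeps' orderings are clearly
separated; the acceptance suite runs a 200-run desk scale.

Design choices where the source material was open:

* **Density sweep randomization** — each replicate redraws the random edges
  added to the path network, so condition means average over network
  realizations as well as landscapes.
* **Inequality timing** — the Gini coefficient is computed on final
  payoffs, i.e. inequality of what agents ended up with.
* **Cross-run averaging** — runs end at different rounds, so per-step
  summaries pad every run with its final values out to a configurable
  reporting `horizon` (default 50) before averaging.
* **Gini variant** — the population (uncorrected) coefficient, with the
  all-zero vector mapped to 0; no small-sample correction.

## What the generators do and do not emulate

The synthetic world is exactly the stated one: i.i.d. uniform skills over
cells and agents, uniform random starting positions, signal-plus-noise
payoffs, and the path-to-complete network family. It does **not** emulate
correlated or clustered skills, payoff structure aligned with skills, agent
turnover, or communication costs. A green qualitative test therefore
establishes that the *mechanism* (copying collapses exploration; pooled
perception widens it; efficient networks amplify whichever mode dominates)
operates in this stated world — not that the effect sizes transfer to any
particular empirical setting.

## Known limitations

* The Perlin parameterization is a documented choice, not a recovered
  ground truth; ruggedness (hence effect sizes) varies with it. At the
  200-run desk scale two of the network-crossing comparisons (the max-payoff
  gaps between path and complete networks at `p = 0` and `p = 1`) are
  directionally correct but not separable at the suite's α = 0.01 — the
  cross-run standard deviation of best-member payoff is large relative to
  those gaps, and resolving them cleanly needs replication near the
  harness's 1000-run default.
* Pure R throughout; a single 100 × 100, n = 16 run costs ~25 ms, which is
  ample for the shipped protocols but would motivate compiled kernels for
  much larger grids or populations.
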