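---
title: "The crowded selfish-herd model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crowded selfish-herd model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdherd)
```

## The model

`crowdherd` simulates the evolution of movement strategies in a population
of selfish prey agents whose mobility is restrained by crowding. The world
is a wrapped-around (torus) square lattice; each cell is vacant or holds
exactly one agent, abstracting the body or territory of one individual.
Predation is implicit: after each generation of movement, the agents that
accumulated the fewest neighbours — the most exposed individuals under a
limited domain of danger — are removed and replaced by offspring of the
survivors. No predator agent, alignment rule, speed or group-level reward
is built in; whatever collective behaviour appears must emerge from
individual-level selection alone.

### Perception and movement

At each time step every agent acts once, in a fresh uniform random
permutation, and each decision reads the lattice as it stands at that
agent's turn (asynchronous sequential updating). An agent perceives:

* the occupancy states (0/1) of its four adjacent cells, in the fixed
  N, S, E, W convention (north is `y - 1`);
* the neighbourhood sizes of those four cells and of its own cell — the
  number of occupied cells in the Moore window of radius `r` (default 1),
  each divided by the window maximum `(2r+1)^2 - 1 = 8`;
* one uniform random value in `[0, 1)` (allowing mixed strategies);
* a constant bias of 1.

These 11 inputs feed a fully connected two-layer linear network with 4
outputs, one per cardinal direction; the agent attempts to move to the
direction with the largest output (exact ties broken uniformly at random).
Linear activation is the minimal choice consistent with an argmax readout:
any monotone activation yields the same decisions, so nothing is lost.
Note that the querying agent itself is counted by the windows of its
adjacent cells — it occupies a real cell and the window sum makes no
exclusion.

A move into a vacant cell always succeeds. A move into an occupied cell is
blocked — the crowding effect — unless a uniform draw falls below
`p_transit`, in which case the two agents swap cells atomically. At
`p_transit = 0` bodies are impenetrable; at `p_transit = 1` transit is
unhindered, recovering the classic selfish-herd setting in which a border
individual can always push into the group interior. A displaced agent keeps
its own turn later in the same step if it has not yet acted; there are no
cascading pushes.

### Scores and selection

Over a generation of `T` steps the package records, once per step after all
agents have acted:

* the **neighbourhood score** `S^N` of each agent — the mean of its
  per-step neighbourhood sizes (range 0–8 at `r = 1`); this is the fitness
  proxy, and the `round(mu * N)` lowest scorers are removed each
  generation (ties at the cutoff broken uniformly at random);
* the **mobility score** `S^M` — the fraction of the `T - 1` transitions
  between consecutive recorded positions in which the agent changed cells;
* the **conditional leave-probability profile** — for each neighbourhood
  size `n`, the frequency with which an agent whose settled neighbourhood
  size was `n` at the end of step `t` changed cells during step `t + 1`.

Each removed agent is replaced by an offspring of two distinct survivors
drawn uniformly at random: every weight is copied from either parent with
probability 1/2 (uniform crossover) and perturbed by a Gaussian draw with
variance `5e-4` (sd ≈ 0.0224). Survivors carry their genotypes over
unmodified. Parents are drawn without niching or spatial structure, and
every generation starts from a fresh uniform random placement, so kin and
group selection are excluded by construction.

Two timing conventions deserve note, both settled once and used
everywhere. First, neighbourhood sizes enter the score as read from the
settled end-of-step configuration, not mid-step; on constructed
configurations (an isolated agent; a fully enclosed one) the profile
boundaries are exact — `P(leave | 0) = 1`, `P(leave | 8) = 0` under full
blocking — while in dense dynamic populations mid-step traffic can blur
interior bins slightly. Second, the mobility sum runs over the `T - 1`
recorded transitions and is normalised by `T - 1`; the deviation from a
`1/T` normalisation is at most `1/T` and vanishes at study scales.

### Strategy analysis

The genotype likelihood `L(a, b) = 1 - mean(|w_a - w_b|)` measures strategy
similarity (1 only for identical networks; possibly negative for very
distant ones — documented, not clipped). Reference strategies are built as
the element-wise mean weight table of the whole population at an archived
epoch generation *of the same run*, because the signs of evolved weights
are run-specific. `strategy_embedding()` then positions every agent by its
likelihood to the coward/explorer/dodger references, and `epoch_summary()`
reports population means at chosen epochs, with plateau boundaries detected
by a deliberately simple smoothing-and-dominant-jump heuristic (the phase
structure is usually read off the phase-plane plot by eye; the detector is
plumbing, not an inferential method).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `width`, `height` | 120, 120 | lattice cells per side (torus) |
| `n_agents` | 200 | population size N |
| `steps` | 2000 | time steps per generation T |
| `generations` | 3000 | generations G |
| `radius` | 1 | Moore radius of the neighbourhood domain |
| `kill_fraction` | 0.05 | truncation fraction mu (10 agents per generation) |
| `mutation_variance` | 5e-4 | per-weight Gaussian mutation variance |
| `p_transit` | 0 | squeeze-through probability |
| `init_weight_range` | 1 | initial weights uniform on [-1, 1] |

The defaults are the full-scale study conditions. `herd_config(profile =
"scaled")` switches to T = 500, G = 1500, the desk-scale profile used by
the package's own analyses and acceptance checks; all other values are
unchanged. The kill fraction mostly affects how crisp the phase transitions
look; the radius generalises the danger domain (the window fits the lattice
or the configuration is rejected); mutation variance should stay at or
below about `1e-3` or late states become noisy.

The initial-weight distribution is not dictated by the model — only an
emergent evolved scale (mean |w| around 0.7) is meaningful — so uniform on
[-1, 1] was chosen once and exposed as `init_weight_range`. On the mutation
scale: with variance `5e-4`, the probability that at least one of the 44
links of an offspring receives a "considerable" mutation, i.e. larger than
10% of a typical evolved mean absolute weight of 0.7, is
`1 - (1 - 2 * pnorm(-0.07 / sqrt(5e-4)))^44` ≈ 7.4% per offspring — a small
but steady supply of behaviourally relevant variants.

## Reproducibility and the two engines

All randomness — placement, per-step agent order, the noise input,
tie-breaks, squeeze-through draws, selection tie-breaks, parent choice,
crossover and mutation — is drawn from R's global RNG in one fixed,
documented sequence, so `set.seed()` (or `config$seed`) makes a run
reproducible to the byte, logs included.

The generational loop exists twice on purpose. The compiled engine
(`engine = "cpp"`, the default) maintains an incrementally updated field of
Moore-window counts so a movement decision costs a handful of reads; swaps
leave the occupied set, and therefore the whole count field, unchanged. The
plain-R reference engine (`engine = "r"`) is built from the exported
operations (`place_agents()`, `build_percept()`, `decide_direction()`,
`attempt_move()`, `select_and_reproduce()`) with explicit loops that
consume the RNG stream in exactly the same order. Given the same seed the
two produce bit-identical trajectories, scores, killed sets and offspring
weights; the test suite asserts this end to end, and additionally checks
the compiled engine against a third, self-contained re-simulation kept in
the test helpers. Numerical note: network outputs are accumulated
sequentially over inputs in both engines so that exact-equality tie
detection agrees bitwise; ties at the argmax occur with probability zero
for evolved (continuous) weights but matter for hand-set fixtures such as
the all-zero genotype.

Degenerate inputs are handled explicitly: `T = 1` leaves the mobility score
undefined (`NA`), an empty score vector is an error, profile bins with no
occasions are `NA` rather than 0, and a population exceeding lattice
capacity is rejected.

## What the simulations show — and at which scale

The model's characteristic dynamic under full blocking is a strategy
succession: random walkers, then *cowards* (stay with any neighbour; many
small groups), then *explorers* (leave cells with few neighbours; large
stationary herds), then *dodgers* (leave even moderately accompanied
border positions), whose constant border departures produce elongated
moving herds and pull the population mean neighbourhood score down to
about 2. With unhindered transit (`p_transit = 1`) the explorer state is
terminal: border agents squeeze inward, exposure is shared equally, and
cohesive stationary herds of 4–5 neighbours persist. These end states are
defined over long generations (T = 2000) and thousands of generations.

Two properties of the **scaled profile** (T = 500, G = 1500) matter when
reading its outputs; both are measured by the package's own test suite so
that passing checks are not over-interpreted:

* The generation mean `S^N` is depressed relative to long generations,
  because every generation starts from a uniform random placement and a
  substantial fraction of a short generation is spent assembling herds
  before the score plateaus. The suite runs a hand-built herd-forming
  strategy at both lengths: it averages `S^N` above 3 over 2000 steps but
  below 3 (around 2.3) over 500 steps while reaching a similar
  end-of-generation state. Final-state scores from short-generation runs
  are therefore conservative, and thresholds calibrated on long
  generations (such as the 4–5 neighbour band of stationary herds) are
  not directly attainable at T = 500.
* Selection acts on a 4-fold noisier score estimate, so transitions that
  need a weak fitness gradient — especially the escape from the coward
  plateau — arrive later in generation count than at T = 2000, or not
  within G = 1500 at all. In the scaled acceptance runs the full-blocking
  populations settle near `S^N` ≈ 1.8–1.9 in a low-mobility clustered
  state (the late leave-probability at 1–2 neighbours stays near 0 rather
  than rising towards 1), and the `p_transit = 1` populations are still
  aggregating when the run ends (final `S^N` around 2). The corresponding
  acceptance checks on the late-epoch profile shape and on the
  stationary-herd score band are therefore expected to fail at this scale,
  and are left failing rather than widened; epoch positions and late-state
  profiles should be read from full-scale runs.

The simulator is also the package's own data generator for testing: the
fixtures (`make_fixture()`) pin hand-placed lattices and hand-set genotypes
for exact expectations, and all stochastic tests run the real model at
reduced sizes. What those tests demonstrate is internal correctness of the
rules, scores and evolution operators — they do not, and cannot, validate
the biological realism of the lattice abstraction itself (volume-less
point models, off-lattice movement, real predators and diagonal moves are
all out of scope).

## Known limitations

* One agent per cell and four-neighbour movement: no diagonal moves,
  multi-cell bodies or continuous space.
* Predation is a rank-order removal rule; there is no predator behaviour,
  confusion effect or attack geometry.
* The generation counts at which the later transitions arrive (the escape
  from the coward plateau, and the eventual collapse of explorer herds into
  moving dodger aggregates) are sensitive to details the model family does
  not pin down — notably the initial weight scale and the exact ordering
  perturbation — and in this implementation can exceed the conventional
  epoch labels (80/200/1000) by a wide margin. Treat `epoch_generations`
  as archiving labels, and locate a run's actual phases from its
  phase-plane plot or `epoch_summary()`.
* The update order is a fresh uniform permutation each step; the model's
  robustness to other orderings that avoid fixed-order bias has not been
  exhaustively explored and the permutation scheme is deliberately kept a
  single documented choice.
* Full-scale evolutionary runs are long; the compiled engine covers the
  study conditions in minutes per run, but large replicate campaigns (the
  hundreds-of-runs regime behind violin summaries) remain a batch job via
  `scan_ptransit()` or the CLI rather than an interactive analysis.
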