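---
title: "A disordered Boolean lattice model of genetic disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A disordered Boolean lattice model of genetic disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The model and its assumptions

`morbnet` implements a deliberately minimal picture of a genetic disease:
a phenotype emerging from the interplay of a fixed genetic predisposition
and a fluctuating environment, mediated by a regulatory network. The
network is an `H × L` lattice of Boolean gates — `H` parallel pathways
(input width) of `L` layers — evaluated feed-forward in a single pass.
Three idealizations do most of the work:

* **Locality.** Only neighbouring pathways interact, through diagonal
  edges `(k, j) → (k±1, j+1)` drawn independently with the branching
  probability `b`. The within-pathway edge `(k, j) → (k, j+1)` always
  exists; edges that would leave the lattice are omitted (no periodic
  boundary), so in-degrees are 1–3.
* **Monotone logic.** Every node is an AND (probability `a`) or an OR
  (probability `1 − a`); there is no NOT. A node can only be active if at
  least one input is active, so removing function can only remove
  activity. This is what makes "loss of function" well defined: for any
  input, the defect network's active outputs are a subset of the healthy
  network's.
* **Acyclicity.** No feedback: the evaluation is a single sweep from the
  input layer to the output layer, comparable to a steady-state
  approximation. Layer-1 nodes carry no gate logic — their state is the
  environment bit, masked to 0 if the node is defect.

The *disease genotype* is a set of `D` permanently inactive nodes placed by
an Eden growth process with teleportation (parameter `d`), and the
*environment* is a binary vector whose bits fluctuate as independent
two-state Markov chains. Each time step the same input is pushed through
the healthy and the defect network and the pair of outputs is classified:
A (equal), B (reduced but non-zero defect output), C (zero defect output
only), D (zero healthy output).

## Parameters

| Parameter | Meaning | Range | Default |
|---|---|---|---|
| `H` | pathways (input/output width) | ≥ 1 | required |
| `L` | layers (pathway length) | ≥ 1 | required |
| `a` | AND-gate fraction (sensitivity vs robustness dial) | [0, 1] | 0.5 |
| `b` | branching probability per diagonal edge (pathway cross-talk) | [0, 1] | 0.5 |
| `D` | number of loss-of-function nodes | 0 .. `H·L` | 5 |
| `d` | Eden clustering: 1 = one connected cluster, 0 = uniform scatter | [0, 1] | 1 |
| `I` | input activity: P(redrawn bit = 1) | [0, 1] | 0.5 |
| `change_prob` | per-bit preselection probability per step | [0, 1] | 0.2 |
| `steps` | time steps per run | ≥ 1 | 1000 |
| `replicates` | runs per sweep grid value | ≥ 1 | 100 |

The defaults for `steps`, `replicates` and `change_prob` are the standard
study conditions for the sweep figures; the environment time scale
(`change_prob`) only stretches the incidence curves in time, which is why
it is exposed as a config key rather than varied in the sweeps.

## Design choices in the generator

Several points of the verbal model admit more than one reading; the
package fixes them as follows.

* **One Bernoulli draw per diagonal.** A node may gain *both* diagonal
  out-edges, each drawn independently with probability `b`. The
  alternative (one draw choosing a single neighbour) cannot produce
  in-degree 3, which the model explicitly allows.
* **Gate assignment is i.i.d.** Each node is AND with probability `a`
  rather than an exact-count shuffle; `a` is a ratio in expectation. Tests
  therefore compare ensemble AND fractions against binomial error bars,
  not exact counts.
* **AND over realized edges.** A border AND node with two realized inputs
  needs exactly those two. Treating missing boundary edges as
  permanently-0 inputs would make every border AND dead and would break
  the exact identity `output = input` of the `b = 0`, `D = 0` lattice.
* **"Current cluster" = most recently nucleated cluster.** When the Eden
  process teleports, the new node becomes the nucleus and subsequent
  growth steps attach to *its* cluster, not to the union of all defect
  nodes. Growth adjacency uses the realized undirected edges of the
  lattice (a diagonal neighbour counts only if the edge exists).
* **Growth dead ends teleport.** If growth is drawn but the current
  cluster has no free neighbour, the step falls back to teleportation and
  the `teleport_fallbacks` counter records it, so analyses can condition
  on pure-growth placements (e.g. the d = 1 ⇒ one-cluster contract).
* **Defects may sit in any layer**, including the input and output layers;
  the location statistic `λ = mean(j)/L` ranges over `[1/L, 1]`, with
  `λ → 1` meaning damage proximal to the phenotype layer.
* **Preselected environment bits are redrawn, not toggled.** A preselected
  bit is set to 1 with probability `I` regardless of its old value, so it
  may keep its value by chance; this gives the per-bit flip rates
  `change_prob·I` and `change_prob·(1 − I)` that the tests verify.

## Time-series classification and statistics

A step is classified with the *current* input, then the environment
fluctuates, so step `t`'s case corresponds to the input at `t`. Lethal
steps are per-step phenotype labels, **not absorbing states**: the run
categories Cx and Dx exist precisely because one time line can contain
lethal and non-lethal stretches. The run category is a pure function of
the set of cases present: D present → `Dx` if A, B and C all occurred,
else `D`; else C present → `Cx` if both A and B occurred, else `C`; else
`B` if B occurred, else `A`. Case sets the x-categories do not literally
cover (e.g. `{D, B}` without A or C) collapse onto the plain lethal label,
the conservative reading.

Incidence statistics are run-length encodings of the case sequence:
maximal B-runs are symptomatic episodes, maximal A-runs symptom-free
episodes, C/D steps break episodes and belong to neither, so episode
lengths plus lethal step counts always total the series length. Chronicity
is reported continuously — the fraction of B steps and the A↔B switch
rate — rather than thresholded into "chronic"/"acute" labels, since the
model itself draws no hard boundary; all-B (`1, 0`) and strict alternation
(`0.5, 1`) are the two pure signatures.

## Sweeps and the phase transition

Sweeps (`sweep_input_activity()`, `sweep_gate_ratio()`,
`sweep_location()`) run fresh network/defect/environment seeds per
replicate, derived deterministically from the master seed, and report the
exact fractions of replicates per run category (they sum to 1 by
construction). The location sweep bins each replicate's own `λ` into 10
equal-width bins over `[1/L, 1]` by default; empty bins are reported with
`n = 0` and `NA` fractions, never fabricated.

`estimate_transition()` takes the dominant (argmax, ties broken toward the
lexicographically earlier label) category per gate-ratio grid value and
returns the midpoint between the largest `a` dominated by a non-lethal
category (A, B or Cx) and the smallest larger `a` dominated by a lethal
one (D or Dx); if no flip exists it errors rather than extrapolating. On a
0.1-spaced grid the estimate is resolved to half a grid step. At the study
conditions (`H = L = 20`, `b = 0.8`, `D = 5`, `d = 1`, `I = 0.8`, 50
replicates × 500 steps), the flip lands at the grid interval around
`a ≈ 0.5`, the model's analogue of the directed-percolation transition:
below it most time lines keep non-zero output (cases A/B), above it the
healthy network itself goes dark (case D dominates).

## State-space enumeration

For small `H` all `2^H` inputs are propagated at once
(`enumerate_statespace()`), inputs ordered by the binary number they
represent, with bit `k − 1` of the code holding pathway `k` (pathway 1 is
the least significant bit). Because evaluation is deterministic, the
per-layer number of distinct states can only decrease, and two inputs that
merge at some layer stay merged forever; both invariants are tested, along
with exact agreement against a naive per-node oracle. The compression
`1 − n_phenotypes/2^H` quantifies funnelling — the mechanism by which many
environments map onto few phenotypes, i.e. robustness. The infinite-length
limit (all outputs eventually frozen on or off) is checked only as a trend
in layer-wise counts, not asserted at finite `L`. An enumeration budget
guard (`max_n = 20` by default) refuses wider networks loudly instead of
exhausting memory.

```{r statespace}
net <- build_lattice(8, 10, a = 0.4, b = 0.8, seed = 11)
enumerate_statespace(net, NULL)$distinct_counts
```

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; the global RNG is
  saved and restored around every draw, and the environment process owns a
  private RNG stream so interleaving it with other draws cannot change its
  trajectory. Three seed roles (network, disease, environment) can be held
  fixed independently; sweeps derive per-replicate seed triples from the
  master seed.
* States are stored as 0/1 matrices and propagated with vectorized
  shift-and-count arithmetic: a node is active iff its active-input count
  reaches its threshold (1 for OR, its realized in-degree for AND). This
  is exactly the gate semantics, just evaluated for many inputs or time
  steps at once; a slow per-node oracle in the test suite pins the
  equivalence.
* Serialization (network JSON, config JSON/YAML, provenance-headed CSVs)
  round-trips to identical objects; every CLI output embeds the complete
  configuration and seeds.

## What the generator does and does not emulate

The simulated conditions are the model's own: Bernoulli lattices,
uncorrelated gate assignment, i.i.d. per-bit environment fluctuations.
Real regulatory networks have long-range links, hubs, feedback, correlated
environments and NOT-like regulation; none of these are represented, so
passing tests certify the model's internal consistency and its stated
limiting behaviours, not fidelity to any specific biological system. In
the same spirit the tests use problem sizes chosen for statistical
resolution — 20 × 20 lattices with 50 replicates × 500 steps for the phase
scan, hundreds of small random networks for the exhaustive state-space
checks, thousands of placements for the Eden-growth statistics — which are
the package's reference conditions, comfortably sufficient to resolve the
transition to one grid step.

## Known limitations

* Exhaustive enumeration is exponential in `H`; beyond `H ≈ 20` only the
  Monte-Carlo path is practical.
* The transition estimator reports a grid-interval midpoint; it does not
  fit a critical exponent or attempt sub-grid resolution.
* Run categories compress a whole time line into one label; time lines
  that change character midway (e.g. late-onset lethality) are visible
  only through the episode and chronicity statistics.
* Damage-spreading analyses, evolving/selected networks and long-range
  links are out of scope.
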