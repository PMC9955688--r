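---
title: "Heterogeneous random Boolean networks: model, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous random Boolean networks: model, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbnhet)
```

## The model

A random Boolean network (RBN) is a set of N binary nodes, each updated by a
fixed Boolean function of its in-neighbors. RBNs are classical abstractions of
gene regulatory networks: a node is a gene, its state is expressed/unexpressed,
and its rule summarizes the combinatorial logic of its regulators. In the
classical (Kauffman) setting every node has exactly K regulators chosen
uniformly at random, all nodes update synchronously, and each rule-table entry
is 1 with the same bias p. Depending on K and p the dynamics are ordered
(perturbations die out), chaotic (they propagate), or critical, near the phase
boundary

$$K_c = \frac{1}{2p(1-p)},$$

so that `critical_connectivity(0.5)` is 2. This package generalizes the
classical model along three independent axes, each switchable between a
homogeneous (`Ho`) and a heterogeneous (`He`) variant:

* **Structure (S).** Node out-degrees are drawn from a distribution:
  Poisson(K) as the homogeneous contrast, or a discretized exponential with
  mean K (variance K² instead of K — markedly heavier-tailed) as the
  heterogeneous one. `degree_spec()` describes the choice and
  `wire_from_out_degrees()` attaches each out-edge to a uniformly chosen
  target (self-loops allowed).
* **Time (T).** `build_schedule()` assigns each node an update period P_a:
  synchronous updating (all P_a = 1) is homogeneous; under out-degree updating
  P_a = max(K⁺_a, 1), so the more nodes a node affects the more slowly it is
  refreshed; the "ceil" strategy gives every node the single shared period
  ⌈K⌉. All nodes due at step t read the state at step t−1 — there is no
  within-step cascade, so trajectories are deterministic given the model,
  schedule, and initial state.
* **Function (F).** `bias_spec()` draws a per-node bias p_a: a point mass at
  0.5 is homogeneous; triangular, truncated-Gaussian, or uniform distributions
  (mean 0.5 by default) give each gene its own expression propensity.

`case_label()` names the eight combinations (`"HoS-HoT-HoF"` through
`"HeS-HeT-HeF"`, abbreviated 3Ho and 3He at the extremes).

## Complexity as a criticality proxy

For a trajectory of T states, each node's temporal series gives an empirical
bit frequency; its normalized Shannon entropy I ∈ [0, 1] is 0 for a frozen
series and 1 for a balanced one. Complexity is defined per node as

$$C = 4\,I\,(1 - I),$$

maximal (1) at I = 0.5 where change and stability balance, and the network
complexity is the plain average of node complexities
(`trajectory_complexity()`). Ordered dynamics give low I and low C, chaotic
dynamics give I near 1 and low C, and the measure peaks near the order–chaos
transition, so complexity-versus-K curves (`complexity_curve()`) locate and
quantify criticality: a broader high-C region means critical-like behavior
over a wider parameter range. `curve_auc()` (trapezoidal area) and
`crossover_k()` (the grid point from which one curve dominates all others
through the end of the grid) summarize such sweeps.

Entropies use the plug-in frequency estimator over the full series, initial
state included, with no burn-in discarded and no bias correction. This is a
deliberate choice: with short runtimes the approach to an attractor carries
information about the regime (an ordered net that freezes early scores lower
than one with a long transient), and any burn-in rule would add an arbitrary
parameter. The consequence — worth keeping in mind when comparing against
attractor-based analyses — is that C depends on T, and single short runs have
broad distributions across network realizations.

## Perturbations and antifragility

The stressor protocol (`perturbation_protocol(x, o, t_max)`) flips `x`
randomly chosen node states whenever the step index is a positive multiple of
`o`. Perturbations act after the step update, never on the initial state, and
the recorded trajectory contains the perturbed states. The perturbation degree

$$\Delta x = \frac{X \cdot T/O}{N \cdot T} = \frac{X}{N\,O} \in [0, 1]$$

is the expected fraction of node-steps flipped. `fragility()` runs the same
model, schedule, and initial state with and without the protocol (a paired
design, so the difference isolates the stressor) and returns

$$A = -\Delta\mathbb{C} \cdot \Delta x, \qquad
  \Delta\mathbb{C} = C_{\text{perturbed}} - C_{\text{baseline}},$$

with A < 0 antifragile (the system gains complexity from noise), A ≈ 0
robust, and A > 0 fragile. `mean_fragility()` averages A over freshly
generated (model, initial state) pairs and reports the standard error across
replicates — the paired single-run values are noisy, and sign claims should
only ever be read off ensemble means with their errors. Regenerating the
model each replicate is the default; `regenerate = "init_only"` reuses one
network with fresh initial states for within-network averaging.

## Generator conventions and numerical choices

Several constructions are under-determined by the verbal model; the package
fixes them as follows.

* **Wiring.** Each node's K⁺ out-edges target independently and uniformly
  chosen nodes; duplicate arcs are collapsed with redraws so in-neighbor lists
  contain distinct regulators (equivalently: min(K⁺, N) distinct targets
  sampled without replacement). Distinct regulators keep the in-degree equal
  to the number of table inputs.
* **Exponential discretization.** Exponential out-degrees are continuous
  draws with mean K rounded to the nearest integer, floored at 0; leaf nodes
  are allowed (`floor_at_one = TRUE` switches to flooring at 1).
* **Zero in-degree nodes.** Random wiring can leave a node without
  regulators. Such a node holds a one-entry table: whenever it updates it
  takes that constant value, i.e., it freezes from its first update on.
* **Zero out-degree nodes.** Under out-degree updating, P_a = max(K⁺_a, 1):
  a node that affects nothing has no reason to be slow, and a zero period
  would be undefined.
* **Ceil period.** The shared period is ⌈K⌉ of the sweep point (a smooth,
  K-dependent homogeneous-in-time contrast); `ceil_use_max = TRUE` uses the
  maximum realized out-degree instead.
* **Truncated Gaussian biases.** Rejection sampling until the draw lands in
  the domain — exact support, reproducible from the seed.
* **Triangular biases.** Inverse-CDF sampling with mode at the stated mean on
  the stated domain; an off-center mean simply skews the triangle.
* **Table indexing.** The input tuple is encoded with the first listed
  in-neighbor as the most significant bit; the convention is arbitrary but
  fixed, and serialization (`write_rbn_model()`) round-trips losslessly.
* **Large in-degrees.** An explicit 2^k lookup table is stored only for
  k ≤ 16 (`options(rbnhet.max_table_k = ...)`). Heavier nodes — which heavy-
  tailed wiring at K ≈ 10 does produce — use a reproducible pseudo-random
  Boolean function instead: a per-node 64-bit seed is mixed with the input
  tuple by a splitmix-style hash and thresholded at p_a. Outputs are
  i.i.d. Bernoulli(p_a) across input tuples, exactly the law of a sampled
  table, at O(k) memory.
* **Seeding.** Every stochastic stage derives its seed from
  `derive_seed(master, ...path)` — a stable hash of labels, grid values, and
  replicate indices kept below 2³¹. Adding grid points or replicates never
  perturbs existing ones, and identical configurations reproduce bit-identical
  results. The inner simulation loop is C++ (Rcpp), but all random draws
  (degrees, biases, tables, initial states, flip targets) happen in R, so
  reproducibility is governed entirely by R's RNG.

## What the generator emulates — and what it does not

The synthetic ensembles emulate the statistical signatures of regulatory-like
networks: heavy-tailed influence (exponential out-degrees), separated
timescales (slow hubs), and gene-specific expression propensities (per-node
bias). They do not emulate real regulatory features such as correlated
in/out-degrees, motif enrichment, modularity, canalizing functions, or
plasticity of wiring. One structural subtlety deserves emphasis: because
out-edges target uniformly chosen nodes, the realized in-degree distribution
is close to Poisson however heavy-tailed the out-degrees are. Out-degree
heterogeneity therefore acts on the dynamics mostly through the update
periods (when out-degree updating is active) rather than through the rule
inputs, and its standalone effect under synchronous updating is weak. Passing
ensemble tests consequently show that the measures behave correctly on these
idealized ensembles — not that any particular biological network is critical
or antifragile.

## Problem sizes used in the checks

The test suite and the acceptance script run reduced but statistically
meaningful configurations, chosen so the full battery completes comfortably
on one CPU: classical-regime ensembles at N = 50, T = 200, 200 networks per
K; the eight-case sweep at N = 100 over K ∈ [4, 8] in steps of 0.5 with 100
networks per point and T = 500; fragility at N = 100, T = 200, X = 40, O = 1,
200 replicates per connectivity; and the bias-symmetry comparison at four K
values with 100 networks each. Full-scale sweeps (45 K-points, 1000 networks,
T = 2000) are available through the same functions by raising the arguments.

## Known limitations

* Complexity is transient-sensitive by design (see above); comparisons across
  different T are not meaningful.
* The out-degree construction leaves in-degrees near-Poisson (see above);
  studies that need heavy-tailed *input* distributions should construct
  topologies directly via `rbn_model_from_parts()`.
* Attractor enumeration, basin analysis, and alternative impact measures are
  out of scope; trajectories and their entropies are the only observables.
* The hashed-rule representation cannot enumerate its full table; it is
  exact for simulation and serialization but not for rule inspection.
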