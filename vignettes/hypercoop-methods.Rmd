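---
title: "Cooperation thresholds for public goods games on hypergraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation thresholds for public goods games on hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercoop)
```

## The model

`hypercoop` studies the evolution of cooperation when individuals interact in
*groups* rather than in pairs. The population is a connected hypergraph: `N`
nodes (individuals) and `E` hyperedges (groups), each hyperedge joining
`g_e >= 2` nodes. Each node belongs to `k_i >= 1` hyperedges.

Every hyperedge hosts a public goods game. A cooperator (`s_i = 1`) invests a
cost `c = 1` in each of its groups; defectors invest nothing. In a group of
order `g_e` the pot is multiplied by a local synergy factor `R_e = r * g_e`
and shared equally, where `r` is the *global* synergy factor. Averaging over
its `k_i` games, node `i` earns

$$u_i(\mathbf{s}) = \frac{r}{k_i} \sum_{e \ni i} \sum_{j \in e} s_j - s_i.$$

Fitness is exponential in payoff, `f_i = exp(delta * u_i)`, with selection
strength `delta` in `[0, 1)`; the fitness of a group is the mean fitness of
its members. `delta = 0` is neutral drift. All analytic results here are
weak-selection results (`delta << 1`), and the simulations that check them
use `delta = 0.025` unless stated otherwise.

## The five update mechanisms

Evolution proceeds by asynchronous updates: at each time step one focal node,
chosen uniformly at random, revises its strategy through a two-stage
selection — first a hyperedge adjacent to the focal node, then an individual
inside it:

| code | hyperedge choice | individual choice | adoption |
|------|-----------------|-------------------|----------|
| HDB  | proportional to group fitness *excluding* the focal node | proportional to fitness, excluding the focal | unconditional |
| HIM  | proportional to full group fitness | proportional to fitness, *including* the focal | unconditional (self-selection keeps the strategy) |
| GMC  | proportional to full group fitness | uniform among the others | unconditional |
| GIC  | uniform | proportional to fitness among the others | unconditional |
| HPC  | uniform | uniform among the others | Fermi rule `f_j / (f_i + f_j)` |

Two modelling choices deserve comment, because the verbal description of the
mechanisms leaves them open:

* **HDB group fitness.** With the focal individual removed, the group
  fitness is normalized as the *mean over the remaining `g_e - 1` members*,
  consistent with group fitness being a mean. The normalization matters only
  when adjacent hyperedges differ in order.
* **HPC comparison.** The probability of adopting the peer's strategy is
  `f_j / (f_i + f_j)`. With exponential fitness this is exactly the Fermi
  rule `1 / (1 + exp(-delta (u_j - u_i)))` at inverse temperature `delta`,
  the canonical pair-comparison update.

At `delta = 0` the expected one-step kernels collapse onto higher-order
random walks: HDB, GMC and GIC onto the no-self-loop walk
$\tilde p_{ij} = \sum_e b(i,e) b(j,e) / (k_i (g_e - 1))$, HIM onto the lazy
walk $\hat p_{ij} = \sum_e b(i,e) b(j,e) / (k_i g_e)$, and HPC onto
$\tilde p / 2$ off the diagonal. These identities are asserted at `1e-12` in
the test suite and are the backbone of the neutral-drift checks
(`update_kernel()` exposes the exact kernels; the C++ sampler used by
`simulate_fixation()` mirrors them).

## Fixation probabilities and the critical synergy factor

Without mutation the dynamics eventually absorb at all-cooperator or
all-defector. `rho_C` is the probability that a *single cooperator placed at
a uniformly random node* takes over; under neutral drift `rho_C = 1/N`
exactly. Cooperation is favoured when `rho_C > 1/N`, and the *critical
synergy factor* `r*` is the smallest `r` for which that holds. `r* < 1`
means the structure promotes cooperation relative to an isolated public
goods game.

The package computes `rho_C` three ways:

1. **Monte Carlo** (`simulate_fixation()`): seeded replicates of the full
   asynchronous dynamics in compiled code, with Wilson 95% intervals. The
   mutant's position is re-drawn uniformly each replicate (the natural
   reading of a "randomly introduced" mutant) rather than averaged
   exhaustively over positions.
2. **Exact** (`exact_fixation()`, `N <= 12`): the dynamics are a Markov
   chain on `2^N` states whose only transitions flip one bit; the absorbing
   linear system is solved sparsely. This is the oracle the Monte Carlo
   engine is validated against (agreement within 3 standard errors across
   mechanisms and `delta` in `{0, 0.05, 0.2}`).
3. **Empirical crossing** (`empirical_rstar()`): the `r` at which
   `rho_C * N` crosses 1. The default estimator evaluates a small grid of
   synergy factors at fixed replicate count and fits a variance-weighted
   line: under weak selection `rho_C * N` is locally linear in `r` and its
   slope is shallow (order `0.25` per unit `r` on the 30-node test ring at
   `delta = 0.025`), so pooling grid points is substantially more precise
   than bisection on single noisy evaluations. Bisection with a
   CI-aware stop remains available (`method = "bisect"`).

## Closed-form thresholds

For each mechanism `r*` has a closed form in structural summaries of the
hypergraph (`critical_r()`): population size `N`, mean hyperdegree and order,
the hyperdegree heterogeneity `eta_k = <k^2>/<k>^2`, the hyperdegree-order
assortativity `zeta`, and two overlap strengths `theta_hat`, `theta_tilde`
summed over ordered pairs of distinct hyperedges. On homogeneous hypergraphs
(constant `k`, constant `g`) the summaries simplify — `eta_k = 1`,
`zeta = g`, `theta_hat = (1 - 1/k) C_ovl` — and the GMC row reduces to

$$r^* = \frac{N/g - 1}{N/k + N(1 - 1/k) C_{\mathrm{ovl}} - g},$$

with `C_ovl` the rescaled overlap strength (`rescaled_overlap()`), the
normalized sum of squared pairwise hyperedge overlaps, ranging from `1/g`
(adjacent groups share single nodes) to 1. A walk-based form
(`rstar_gmc_walk()`) computes the same threshold on arbitrary hypergraphs
from the lazy walk matrix, the stationary hyperdegree distribution and the
shared-hyperedge counts.

Three reading choices in the summary definitions are deliberate, and each is
pinned by an exact identity in the tests:

* the assortativity summand is the *product* `g_alpha * k_i` — the unique
  reading under which `zeta = g` on every homogeneous hypergraph and the
  GMC closed form reduces to the display above;
* overlap sums run over *ordered* pairs `alpha != beta`, required for
  `C_ovl = 1/4` on the weak `(k = 2, g = 4)` family;
* the trailing factor of the walk-based threshold is
  `(sum_e b(i,e) b(v,e)) / k_i`, the reading under which the walk form and
  the closed form agree to `1e-9` on the weak and moderate overlap families
  (numerators and denominators are known rationals there: `249/621` and
  `249/746` at `N = 1000`).

Thresholds can legitimately fall outside `(0, 1)` for extreme structures
(GIC/HPC give `(N - 1)/(N - g) > 1` on homogeneous hypergraphs — those
mechanisms inhibit cooperation); values are returned as-is with a
`promotes_cooperation` flag.

## Generators and what they emulate

The generators construct the structured families used to probe the theory:

* `hg_homogeneous_weak(k, g, n_edges)` — minimal overlap (`C_ovl = 1/g`).
  For `k = 2` it places one node per edge of a simple `g`-regular graph;
  for `k = g` it uses cyclic translates of a Sidon set (all pairwise
  differences distinct), which guarantees overlaps of at most one node
  deterministically; other `(k, g)` fall back to biregular stub matching
  with bounded rewiring.
* `hg_ring_overlap(g, overlap, n_edges)` — a ring of groups, consecutive
  groups sharing `overlap = g/2` nodes (`C_ovl = 1/2` at `g = 4`).
* `hg_dimer_chain(n)` — pairs of order-4 groups sharing 3 nodes, pairs
  linked by single nodes (`C_ovl = 5/8`).
* `hg_window_ring(N, g)` — all `N` sliding windows of `g` consecutive nodes
  on a ring (`C_ovl = 5/9` at `g = 3`).
* `hg_configuration_model(k_seq, g_seq)` — bipartite stub matching with
  swap-repair of duplicate memberships (rejection would be hopeless for
  heavy-tailed sequences) and resampling for connectivity.

A moderate `(k = 3, g = 3)` family with `C_ovl = 13/27` would require a
non-uniform mixture of overlap patterns whose construction is not determined
by the values above; it is deliberately omitted, and the `(3, 3)` overlap
comparison uses the weak (`1/3`) and strong (`5/9`) families only.

These generators emulate *controlled structure*: exact degree/order
sequences and exact overlap multisets. They do not emulate features of
empirical group structure such as community structure, order-hyperdegree
correlations, or heterogeneous overlap profiles, so passing tests on these
families demonstrates correctness of the machinery, not robustness of the
theory on real networks.

## Numerical choices and problem sizes

* Hyperedges are node *sets*; duplicate hyperedges are allowed and count as
  distinct in all overlap sums. Connectivity of the bipartite incidence is
  enforced at construction, because fixation of a single mutant is
  ill-defined across components.
* Walk and kernel matrices are dense; the intended regime is `N` up to a
  few thousand, which covers all families shipped here.
* The Monte Carlo engine draws from R's RNG, so `set.seed()` (or the `seed`
  arguments) fixes entire trajectories bit-for-bit; replicates run
  sequentially from one stream.
* The exact solver is capped at `N = 12` (4096 states) to keep the state
  enumeration cheap.
* Simulation checks in the test suite run at desk scale: neutral-drift
  checks use `2e4` replicates; the simulation-versus-theory crossing check
  uses the 30-node window ring at `1e5` replicates per grid point, five
  grid points on `[0.25, 0.75]`. At that size the weighted-fit crossing has
  a standard error near `0.03`, comfortably inside the 15% band around the
  closed-form value `81/163 ~ 0.497`. Full-scale replications (`5e5`
  replicates on `N >= 100` instances) are out of desk-scale reach and are
  deliberately not attempted; widening replicates narrows the intervals
  without changing the estimators.

## Worked example

```{r example}
H <- hg_window_ring(30, 3)
hypergraph_stats(H)
critical_r(H)
```

```{r fixation}
fr <- simulate_fixation(H, "GMC", r = 1.5, delta = 0.025,
                        replicates = 5000, seed = 1)
tidy(fr)
```

The relative fixation probability `rho_C * N` above 1 indicates that at
`r = 1.5 > r* = 0.497` selection favours the invading cooperator on this
structure; close to the threshold the excess over the baseline shrinks
towards zero and needs correspondingly more replicates to resolve.

## Known limitations

* Only the GMC threshold has a walk-based general form; the other four are
  available through their closed forms in the structural summaries.
* No weighted or directed hyperedges, no mutation, no synchronous updates,
  no mixed populations of mechanisms.
* The closed forms are weak-selection, large-time approximations: at strong
  selection or on very small hypergraphs the empirical crossing can drift
  from the closed-form value, which is why the simulation checks quote
  tolerances rather than exact agreement.
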