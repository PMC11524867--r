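---
title: "Counting the isolated-node classes of preferentially cut-and-rewired random networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the isolated-node classes of preferentially cut-and-rewired random networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcro)
```

## The operation

The package studies a two-stage rewiring operation on an Erdős–Rényi
substrate `G(N, P_ER)` that models how localized functional modules in a
brain network might be detached from their neighbourhood and re-attached to
regulatory hub regions.

1. **Cutting.** Every node whose degree lies in the preferential band
   `[k1, k2]` is a *candidate*; each candidate is independently cut with
   probability `p_pcro`, losing **all** of its edges. Unselected candidates
   keep every link.
2. **Rewiring.** After the cut, every isolated node is attached to each of
   `n_hubs` target nodes (default two), chosen as the non-isolated nodes
   whose post-cut degree is closest to the rewiring constraint `k3`.

Isolation has three disjoint causes, and the taxonomy drives everything
downstream: **NIN** (naturally isolated — degree 0 already in the
substrate), **ADIN** (actively deleted — a cut candidate), and **PDIN**
(passively deleted — a surviving node all of whose neighbours were cut).
Their union forms the **common leaves (CLs)**, the nodes that end up shared
by the hubs; the operated network is a homogeneous bulk plus a hub-and-leaf
motif whose size is the quantity of interest.

Default constraints are `k1 = 1`, `k2` = the realized average degree `2L/N`
of the substrate (`"avg_pre"`, kept real-valued), and `k3` = the post-cut
maximum degree (`"max_post"`). Reference parameters throughout are
`N = 100`, `P_ER = 0.05`.

## Closed-form count distributions

`pcro_model()` evaluates the analytic law of each class count. The chain of
approximations:

* The substrate edge count is `L ~ Binomial(N(N-1)/2, P_ER)`. Every
  subsequent quantity is computed conditionally on `L` and averaged over
  this law (`edge_count_pmf()`).
* Conditional on `L`, each node's degree is approximated as
  `Binomial(N-1, P_ECP)` with the *equivalent connection probability*
  `P_ECP = 2L/(N(N-1))` — the edge probability whose expected average
  degree reproduces the realized edge count.
* A node is a candidate when its degree falls in `[k1, k2]`; the in-band
  binomial mass `q_L` gives the candidate count as `Binomial(N, q_L)`,
  mixed over `L` (`nspccp_count_dist()`).
* **ADIN**: binomial thinning of the candidate count by `p_pcro`
  (`adin_count_dist()`); the mean identity
  `E[N_ADIN] = p_pcro E[N_NSPCCP]` is exact.
* **PDIN**: a node of degree `ki >= 1` survives the cut itself (probability
  `1 - p_pcro` inside the band, 1 outside), each of its `ki` neighbours
  lies in the band (each with the size-biased conditional degree law of a
  node that owns the shared edge, `Binomial(N-2, P_ECP)` shifted by one),
  and each neighbour is cut (`p_pcro^ki`). Multiplying, averaging over the
  focal degree law and mixing over `L` gives the node probability
  (`pdin_node_prob()`), and the count is `Binomial(N, p_PDIN)`.
* **NIN**: `Binomial(N, (1-P_ER)^(N-1))` — no equivalent-probability
  approximation enters at the node level.
* **CL**: the three counts are treated as independent and the leaf-count
  law is their discrete convolution (`cl_count_dist()`); the mean adds
  exactly.

### Symbolic constraints inside the mixture

When `k2 = "avg_pre"`, each `L`-term of a mixture resolves `k2 = 2L/N`:
the band tracks the realized average degree, exactly as the operator does
on a realized graph. Band edges stay real-valued and the degree sums run
over the integers in `[ceil(k1), floor(k2)]`; an empty integer band means
probability zero. `"max_pre"` resolves to `N - 1` inside the analytic
band sums — exact for candidate membership, because no realized degree can
exceed the realized maximum, so "degree in `[k1, kMax]`" is the same event
as "degree ≥ `k1`".

### The focal degree law for passive isolation

Two readings exist for the degree law of the *focal* node in the PDIN
derivation: the same size-biased conditional form used for its neighbours
(`pki_form = "edge_biased"`, the default), or the plain substrate degree
law restricted to degree ≥ 1 (`pki_form = "binomial"`). The size-biased
form starves the low degrees (a degree-1 node is the most likely passive
isolate but the least likely endpoint of a random edge), and
`validation_suite()` reports the total-variation distance of both variants
against simulation in every cell so the better-matching form is always
visible. In our validation runs the plain-binomial form tracks Monte Carlo
substantially better, notably when the cutting band is wide; the default
nevertheless stays with the size-biased form, which is the derivation this
package implements, and the flag makes the comparison a one-keystroke
experiment.

### Where the approximations bite

The validation engine (`validation_suite()`, and the acceptance script)
quantifies three systematic effects that the closed forms do not capture:

* Conditional on `L`, in-band indicators across nodes are correlated
  (degrees share edges and their total is fixed), so the
  `Binomial(N, q_L)` candidate-count law overstates the variance; the
  thinned ADIN law inherits this, more visibly the larger `p_pcro`.
* Isolation events are positively correlated (two nodes lacking their
  mutual edge makes both isolations likelier), so the binomial NIN law is
  itself an approximation; noticeable only when `(1-P_ER)^(N-1)` is not
  tiny (small `N` or sparse substrates).
* ADIN and PDIN counts are positively correlated by construction (more cut
  nodes create more passive isolates), so the independence convolution for
  the leaves is narrower than the truth; mild at the defaults, strong when
  the band covers the high degrees.

The means remain accurate (a few percent at worst in our grids) in every
cell — superposition of means is exact — which is why the mean-leaf-count
curve `mean_cl_curve()` is the most robust summary of the theory.

## Numerical choices

* The `L`-mixture support (up to `N(N-1)/2` terms) is truncated to the
  smallest contiguous region around the mode carrying mass
  `≥ 1 - truncation_tol` (default `1e-10`), then renormalized; results are
  insensitive across `1e-8`–`1e-12` (tested).
* The per-neighbour band mass is computed once per `L` and raised to the
  focal degree in log space, avoiding underflow at large `ki`.
* Convolutions are exact outer sums over the integer supports; the tiny
  mass the independence assumption places above `N` is preserved and
  reported as a diagnostic attribute rather than renormalized away.
* Hub ties (several nodes equally close to `k3`) break by ascending node
  id: deterministic and seed-independent. Exact degree matches are not
  required — the hubs minimize `|degree - k3|` — since only `"max_post"`
  guarantees an exact attainer.
* A post-cut graph with fewer non-isolated nodes than hubs raises a typed
  degenerate-network error; the Monte Carlo layer records counts anyway
  (they are classification-level quantities) and tallies the rejection.
* Every stochastic entry point takes a `seed` and restores the caller's
  RNG state, so runs are reproducible without global side effects.

## Validation design

`simulate_counts()` redraws the substrate every sample — the analytic
theory averages over `L`, so validation must too; a fixed-graph mode exists
for diagnostics. Substrates with at most 12 nodes use a fully vectorized
pair-indicator sampler; both samplers implement identical classification
rules and are cross-checked against each other and against
`enumerate_exact()`, which integrates the exact joint law of
`(N_NIN, N_ADIN, N_PDIN)` by brute force over every labeled graph and every
cut subset for `N ≤ 5`. The enumeration is the ground truth that contains
*no* approximation, so Monte Carlo → enumeration convergence validates the
sampler and sampler → closed-form distances then isolate the theory's
approximation error.

Distribution agreement is measured by total variation distance on the union
support of raw (unsmoothed) frequencies. Test-suite and acceptance runs use
`S = 10^4` samples per cell (and `10^5` where the tiny-substrate sampler
makes it free) — at this scale the sampling contribution to a TV distance
is of order 0.01–0.02, small enough to expose the systematic effects listed
above. The generator emulates exactly the study conditions (independent-pair
random substrates); it does not emulate degree-correlated, clustered, or
modular real networks, so agreement here demonstrates correctness of the
formulas under their own assumptions, not their accuracy on empirical brain
graphs.

## Structure metrics

`avg_clustering()` averages the local triangle density over all nodes,
counting degree-<2 nodes as zero; `mean_shortest_path()` averages over
connected ordered pairs and always reports the excluded-pair fraction,
since operated networks are routinely disconnected. Both are delegated to
igraph and verified against brute-force oracles in the tests.

Measured on the final (rewired) graph at `N = 90`, `P_ER = 0.032`, the
curve produced by `metric_curve()` shows clustering *rising* (toward the
0.2–0.25 range as almost every node becomes a leaf of two mutually linked
hubs, each such leaf closing a triangle) and mean path length *falling*
(toward ≈ 3 as paths shortcut through the hubs). Descriptions of this
regime sometimes state the two trends in the opposite direction while
quoting the same limiting values; the limiting values are what our runs
reproduce, and the trend directions follow mechanically from leaf-triangle
formation, so we report the measured directions.

## Network dynamics

The dynamics layer is an interpretation layer: the cited modeling
literature fixes the parameter values (`alpha = 0.5`, `epsilon = 0.05`,
`phi = pi/2 - 0.1`, `sigma = 0.07`) but not the exact coupled equations, so
`simulate_fhn()` implements the standard rotationally coupled
FitzHugh–Nagumo network

$$\epsilon \dot u_i = u_i - u_i^3/3 - v_i + \sigma \sum_j A_{ij}
  [\cos\varphi\,(u_j-u_i) + \sin\varphi\,(v_j-v_i)],$$
$$\dot v_i = u_i + \alpha + \sigma \sum_j A_{ij}
  [-\sin\varphi\,(u_j-u_i) + \cos\varphi\,(v_j-v_i)],$$

with the raw adjacency by default and a degree-normalized variant behind a
flag. Integration is fixed-step RK4; the default `dt = 0.0025` keeps the
step-halving trajectory difference below `1e-3` in sup-norm over a
100-unit window (the steep activator jumps at `epsilon = 0.05` make the
coarser steps that first come to mind visibly insufficient — the
convergence check is part of the test suite). Node phases are the
four-quadrant angle of `(u, v)` about the origin; the Kuramoto order
parameter is the modulus of the mean unit phasor; and a seizure-like
episode is a maximal run with `r > 0.8` lasting more than 8 s under the
configurable model-time→seconds mapping (default 1 s per unit, since no
published mapping exists). Initial conditions default to seeded uniforms on
`[-2, 2] × [-1, 1]`, the box containing the uncoupled limit cycle.

## Worked example

```{r example, eval = FALSE}
model <- pcro_model(100, 0.05, p_pcro = 0.5)
sim <- simulate_counts(100, 0.05, pcro_config(p_pcro = 0.5), S = 1e4, seed = 1)
total_variation(cl_count_dist(model), simulated_dist(sim, "cl"))
mean_cl_curve(model, seq(0, 1, 0.25))
```

## Known limitations

* The closed forms are specific to independent-pair substrates; degree-
  correlated or clustered substrates need a different conditional degree
  theory (out of scope here).
* Only the marginal laws of the three classes are derived; the joint law
  (and hence the exact leaf-count law) is available only from
  `enumerate_exact()` at tiny `N`.
* Repeated application of the operation, per-leaf hub splitting, and
  weighted candidate selection are not modeled.
* The dynamics layer reproduces the qualitative synchronization phenomena;
  published trajectories cannot be matched point-wise because their initial
  conditions and time mapping are not public.
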