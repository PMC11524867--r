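# pcro

Preferential cutting–rewiring of Erdős–Rényi random networks, with
closed-form statistics for the node classes the operation creates.

## The problem

Brain networks are thought to balance cheap, localized modules against
global integration routed through hub regions. A minimal structural model
of that process starts from a homogeneous Erdős–Rényi random network
`G(N, P_ER)` and applies a two-stage **preferentially cutting–rewiring
operation (PCRO)**:

1. every node with degree in a preferential band `[k1, k2]` becomes a
   cutting *candidate*, and each candidate independently loses **all** of
   its edges with probability `p_pcro`;
2. every node left isolated is rewired as a **common leaf (CL)** attached
   to each of two hubs — the non-isolated nodes whose post-cut degree best
   matches a rewiring constraint `k3`.

Isolation has three disjoint causes, and the package's core result is the
probability law of each class count and of their sum:

* `N_NIN` — naturally isolated nodes (degree 0 in the substrate):
  `Binomial(N, (1 - P_ER)^(N-1))`;
* `N_ADIN` — actively deleted nodes (cut candidates): a `p_pcro`-thinning
  of the candidate count, itself a binomial mixture over the substrate
  edge count `L` via the equivalent connection probability
  `P_ECP = 2L / (N(N-1))`;
* `N_PDIN` — passively deleted nodes (all neighbours cut): a
  compound-binomial node probability combining survival of the focal node,
  in-band neighbours, and neighbour cuts;
* `N_CL = N_NIN + N_ADIN + N_PDIN` — the leaf count, computed as the
  convolution of the three laws.

Around the closed forms the package provides a Monte Carlo engine with an
exhaustive-enumeration oracle for tiny substrates, total-variation
comparison machinery, clustering/path-length curves of operated networks,
and rotationally coupled FitzHugh–Nagumo dynamics with Kuramoto-order
seizure-episode detection. It is aimed at researchers in network
physiology and random-graph statistics who want the analytic laws, their
validation, or the operated substrates themselves.

## Worked example

```r
library(pcro)

model <- pcro_model(100, 0.05, p_pcro = 0.5)       # analytic side
sim   <- simulate_counts(100, 0.05, pcro_config(p_pcro = 0.5),
                         S = 1e4, seed = 1)        # empirical side

mean(cl_count_dist(model))                         # 26.73947
mean(sim$counts[, "cl"])                           # 26.9859
total_variation(cl_count_dist(model), simulated_dist(sim, "cl"))
                                                   # 0.04518443
```

The analytic mean says that at `p_pcro = 0.5` the operation converts on
average ~27 of the 100 nodes into common leaves; simulation agrees to a
fraction of a node, and the total-variation distance of about 0.045 shows
the full distributions nearly coincide at the reference parameters. A
single realization:

```r
g <- sample_errn(100, 0.05, seed = 1)
apply_pcro(g, pcro_config(p_pcro = 0.5), seed = 2)
#> PCRO result on 100 nodes
#>   edges: 243 pre-cut, 171 post-cut, 223 final
#>   resolved band [1, 4.86], k3 = 9; hubs: 92, 7
#>   candidates: 44; NIN 2 + ADIN 24 + PDIN 0 = 26 common leaves
```

A command-line wrapper (`inst/cli/pcro-tool`) drives the same functions
from YAML configs with subcommands `generate`, `pcro`, `analytic`, `mc`,
`validate`, `metrics`, and `dynamics`.

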