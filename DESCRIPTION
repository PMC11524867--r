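Package: pcro
Title: Preferential Cutting-Rewiring of Random Networks and Its Count Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the preferentially cutting-rewiring operation (PCRO) on
    Erdos-Renyi random networks: degree-band candidates are probabilistically
    cut loose, and every isolated node (naturally isolated, actively deleted,
    or passively deleted) is rewired as a common leaf to preferentially chosen
    hubs, turning a homogeneous random graph into a heterogeneous hub-and-leaf
    one. Provides closed-form compound-binomial probability distributions for
    the counts of the four node classes and their superposition, a Monte
    Carlo and exhaustive-enumeration validation engine, clustering and
    shortest-path structure metrics, and FitzHugh-Nagumo network dynamics with
    rotational coupling for seizure-like synchronization detection via the
    Kuramoto order parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
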