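Package: strokenet
Title: Whole-Brain Wilson-Cowan Modelling of Stroke with Inhibitory Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates large-scale cortical dynamics with a network of delayed,
    noise-driven Wilson-Cowan neural masses coupled through a structural
    connectome, with homeostatic scaling of local inhibitory weights that holds
    excitatory firing at a target rate. Includes a balloon-Windkessel
    hemodynamic forward model for synthetic BOLD, an in-silico stroke protocol
    (pre-lesion baseline, acute post-lesion, chronic post-recovery), and an
    analysis suite: static functional connectivity and its dynamics (FCD),
    Kuramoto synchrony and metastability, neuronal-avalanche criticality,
    graph modularity and small-worldness on density-thresholded functional
    networks, and maps of long-term excitability change with their spatial
    structure. Synthetic connectome and reference-signal generators make the
    full pipeline runnable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
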