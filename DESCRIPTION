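Package: gfgcoal
Title: Gene-for-Gene Coevolution Simulation and ABC Inference from Host
    and Parasite Polymorphism Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates host-parasite coevolution at a single bi-allelic
    gene-for-gene locus forward in time (deterministic selection recursions,
    binomial genetic drift, recurrent functional mutation), generates
    polymorphism data by a backward-in-time structured coalescent conditioned
    on the simulated allele-frequency paths, summarises samples by unfolded
    site-frequency-spectrum statistics (Watterson's theta, pi, Tajima's D,
    Fu and Li's D and F, Fay and Wu's theta_H, normalised H, and a pairwise
    Manhattan distance between the host and parasite spectra), and infers
    the costs of infection, resistance and infectivity and the population
    sizes by Approximate Bayesian Computation: rejection-based model choice
    with leave-one-out cross-validation and regression-adjusted parameter
    estimation from replicated coevolutionary histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
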