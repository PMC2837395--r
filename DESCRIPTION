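Package: mutatorsim
Title: Multiscale Lattice-Protein Simulator of Mutator Dynamics Under Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ab initio multiscale evolutionary simulator in which the fitness
    and the mutation rate of model cells are computed from first principles:
    27-mer lattice-protein folding stability under the Miyazawa-Jernigan contact
    potential, rigid-body docking thermodynamics over the 144 cube-face docking
    modes, and law-of-mass-action cytoplasmic equilibria. Model genomes carry
    three replication-controlling genes and one mismatch-repair (MMR) gene whose
    functional homodimer concentration sets the mutation rate. The package
    enumerates the 103,346 maximally compact 3x3x3 lattice conformations,
    designs stable seed sequences by Monte Carlo in sequence space, evolves
    finite asexual populations in a chemostat regime under heat-shock,
    stationary-phase and starvation stress protocols, and analyses the rise and
    fall of mutator phenotypes (cause classification, competition experiments,
    constant-fitness drift controls, and local fitness landscapes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    seqinr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
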