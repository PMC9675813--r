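Package: morbnet
Title: Stylized Boolean Lattice Model of Genetic Disease and Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a minimal model of genetic disease in which a
    disordered feed-forward lattice of Boolean AND/OR gates interfaces a
    fluctuating binary environment (input layer) with a functional phenotype
    (output layer). Genetic predisposition is modelled as permanent loss of
    function of network nodes, placed by an Eden growth process with
    teleportation. Provides healthy-versus-defect time-series simulation with
    per-step phenotype classification (no symptoms, symptomatic, lethal
    disease, lethal environment), incidence/episode statistics and
    chronic-versus-acute signatures, parameter sweeps over gate ratio, input
    activity and damage location including detection of the percolation-like
    phase transition, and exhaustive state-space enumeration quantifying the
    funnelling of environments onto phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
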