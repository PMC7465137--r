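Package: glutensim
Title: Coarse-Grained Monte Carlo Simulation of Wheat Gluten Storage Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence profiling and coarse-grained Metropolis Monte Carlo
    simulation of intrinsically disordered wheat seed storage proteins
    (alpha-gliadin and low molecular weight glutenin subunits). Provides
    Kyte-Doolittle and Rose hydropathy profiling, charge census and
    diagram-of-states classification, a bead-per-residue chain model with
    screened Debye-Hueckel electrostatics, explicit counter-ions and
    disulfide restraints in a periodic box, canonical Metropolis sampling
    with simulated annealing, and ensemble observables: radius-of-gyration
    statistics and distributions, Flory scaling fits, shape factors, Debye
    scattering and Kratky curves, residue contact maps and cysteine contact
    networks. Includes generators for gluten-like synthetic sequences and
    reference chain conformations (rod, ideal, self-avoiding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
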