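Package: thermodms
Title: Thermodynamic Energy Models for Combinatorial Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits interpretable thermodynamic genotype-phenotype models to
    combinatorial deep mutational scanning data. Protein abundance is modelled
    as a two-state (unfolded/folded) and ligand binding as a three-state
    (unfolded, folded-unbound, folded-bound) Boltzmann equilibrium, with
    variant free energies given by additive single-substitution terms plus
    optional pairwise energetic couplings. Provides weighted gradient-based
    model fitting with Monte Carlo confidence intervals, linear-model
    baselines, a synthetic-data generator with known ground truth, a greedy
    algorithm for designing fold- and function-preserving combinatorial
    mutagenesis libraries, and structural analysis relating coupling strength
    to residue contacts and backbone proximity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
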