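Package: mrmcdock
Title: Mixed-Resolution Monte Carlo Flexible Protein-Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flexible protein-ligand docking by mixed-resolution Monte Carlo.
    The binding site and ligand are treated with an AMBER-form atomistic force
    field while the remainder of the receptor is coarse-grained with a 12-10
    Go-type native-contact potential on alpha carbons; solvation is implicit
    via a solvent-exposure-dependent distance-dependent dielectric.  Provides
    a Metropolis Monte Carlo engine with configurable protein flexibility, a
    nonequilibrium candidate Monte Carlo (NCMC) move layer with a four-phase
    coupling schedule, a random-pose docking protocol, symmetry-aware ligand
    RMSD, complete-linkage pose clustering and pose-ranking analyses, and
    fully parameterised synthetic receptor-ligand fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    ChemmineR,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
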