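Package: oligovar
Title: Composition Scanning of Dominant Missense Variants in Protein Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how a dominant missense variant destabilizes a homo-oligomeric
    protein assembly by exhaustively scanning every wild-type/mutant composition of
    the oligomer. Reconstructs trimeric biological units from crystal symmetry
    operators, builds head-to-head hexamers by rigid superposition, prepares
    structures (water pruning, protonation at a given pH, displacement-capped
    minimization), introduces point substitutions by rotamer replacement, and scores
    each composition with a molecular-mechanics plus generalized-Born/surface-area
    thermodynamic cycle, reporting apparent binding and folding free-energy changes
    with Coulomb and solvation decompositions pooled by mutation count. Includes a
    finite-difference linear Poisson-Boltzmann solver for surface potential maps and
    isopotential meshes, and hydrophobic/electrostatic surface-patch aggregation
    scoring. Ships synthetic C3-symmetric fixtures so the full pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
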