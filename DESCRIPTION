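Package: helixforge
Title: Desk-Scale Redesign of Four-Helix-Bundle Cytokines with Assay Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for targeted scaffold minimization of four-helix-bundle
    cytokines: helix extraction and interface-role annotation from PDB
    structures, connector-economy topology redesign, cyclic-coordinate-descent
    loop closure with ideal peptide geometry, disulfide-staple scanning,
    mutation transfer, and Kabsch superposition acceptance. Also implements the
    quantitative assay mathematics used to characterize designed variants:
    1:1 Langmuir surface plasmon resonance simulation and global kinetic
    fitting, Boltzmann thermal-shift melting-temperature fitting, and the
    caliper tumor-volume formula. A synthetic-data module generates idealized
    bundles, receptor probes, sensorgrams and melt curves so the whole pipeline
    is testable without external structures or instruments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
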