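Package: firclaw
Title: FIR/LIR Motif Grammar, Phosphopeptide Mass Arithmetic, Binding
    Fits and Interface Analysis for FIP200 Claw Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how autophagy receptors dock onto the
    FIP200 Claw domain through short linear FIR/LIR motifs. Implements
    the consensus FIR core grammar (psi-theta-x-x-gamma, with an acidic
    or phosphoserine/phosphothreonine anchor) with Mode I/II
    phospho-classification and FASTA scanning; monoisotopic
    phosphopeptide masses with b/y fragment ladders and peak
    annotation; one-site fluorescence-polarization binding fits with
    ligand depletion; and structure interface characterization
    (Shrake-Rupley solvent accessibility, buried surface area,
    hydrogen bonds, salt bridges, pocket contacts, rigid
    superposition). Seeded synthetic-data generators cover every input
    class so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
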