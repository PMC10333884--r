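Package: phosdisplay
Title: Phosphomimetic Peptide Phage Display Design and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational workflow for phosphomimetic proteomic
    peptide-phage display (ProP-PD). Designs tiled wild-type plus
    single-glutamate phosphomimetic peptide libraries over disordered
    proteome regions and reverse-translates them into display oligos,
    processes phage-selection sequencing data into normalized peptide count
    tables, computes the phosphomimetic enrichment score (PES) with
    Mann-Whitney significance per bait and phosphosite, fits fluorescence
    polarization saturation and displacement curves (including IC50 to Ki
    conversion under ligand depletion), and ships a seeded simulator that
    generates ground-truth-known proteomes, selections and binding curves
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
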