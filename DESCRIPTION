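Package: mocrlink
Title: Inter-Domain Linker Peptide Analysis for MocR-Family Transcriptional Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical characterisation of the inter-domain
    linker peptides that connect the winged helix-turn-helix (wHTH) DNA-binding
    domain and the aminotransferase-like (AAT) effector domain of MocR-family
    bacterial transcriptional regulators (GabR, PdxR and relatives). Provides
    linker extraction from domain-boundary tables or from multiple sequence
    alignments, residue and dyad (dipeptide) propensity statistics with
    categorical shading conventions, AAindex physicochemical scale profiling
    of linkers versus flanking domains, three-state secondary structure
    fraction summaries, length-binned histograms for subgroup comparisons,
    and a fully seeded synthetic sequence generator with known ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
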