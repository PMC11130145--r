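Package: sbnar
Title: Structure-Based Network Analysis for Missense Variant Pathogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-residue topology scores from a protein structure's
    residue-interaction network (local connectivity, bridging and ligand
    proximity on a weighted heavy-atom contact graph), combines them with
    BLOSUM62 substitution dissimilarity and optional EVE evolutionary scores
    into missense-variant pathogenicity calls, and evaluates calls against
    ClinVar/gnomAD-style labels with ROC, rank-based tests and zero-intercept
    logistic-regression protocols. Includes deterministic synthetic structure
    and variant generators so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
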