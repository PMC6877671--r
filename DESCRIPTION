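Package: hlacascade
Title: Patient-Individualized HLA Ligandome Target Selection and Immune
    Response Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting patient-individualized tumor antigen
    candidates from eluted HLA ligandomes and somatic variant calls, and
    for assessing the resulting immune responses. Implements
    tumor-versus-benign ligandome subtraction cascades for HLA class I
    and class II peptides, position-specific scoring matrix (SYFPEITHI
    style) binding assessment with relative scores, neoepitope window
    scanning with 15-mer extension around mutated residues,
    expression-based candidate curation (CPM normalization, log2 fold
    change, cohort identification frequency), intracellular cytokine
    staining (ICS) positivity criteria with longitudinal response
    classification, and immunohistochemistry scoring arithmetic
    (immunoreactive score, per-HPF means, hot-spot selection,
    Mann-Whitney group comparison). Seeded synthetic-data generators
    with planted ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    edgeR,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
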