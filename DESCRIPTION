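Package: tardiquant
Title: Label-Free Proteomic Quantification and Treatment-Specific Protein
    Selection for Chemical Pre-Treatment Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Peptide peak-area based label-free quantification and candidate
    selection for three-group (untreated / vehicle / treatment) proteomics
    designs, as used to find proteins changed by chemical pre-treatment in the
    anhydrobiotic tardigrade Hypsibius exemplaris. Implements total-sum run
    normalization, peptide relative expression, median roll-up over unique
    peptides, the triplicate-detection filter, per-group Student's t-tests
    against the untreated control, the treatment-specific differential call
    with strict fold-change and vehicle-band criteria, desiccation-survival
    statistics including a Tukey-Kramer test built on the studentized-range
    distribution, and a spike-in simulator of LC-MS evidence tables with
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
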