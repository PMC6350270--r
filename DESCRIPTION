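Package: tevascore
Title: Ex Vivo and In Vivo Drug-Response Scoring for Tumor Explant Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immunohistochemistry readouts from tumor explant
    drug assays and patient-derived xenograft efficacy studies, and scores
    drug response on both arms. Positive-object counts over annotated tumor
    area yield Ki67 (proliferation) and TUNEL (apoptosis) object frequencies;
    a control-normalized ex vivo score (VitroF) and a caliper-volume-based
    in vivo score (VivoF) are computed per drug, paired, and assessed for
    concordance (Pearson and Spearman correlation, least-squares line,
    permutation p-value) to support drug prioritization. A synthetic-data
    generator emulates the explant staining tables, caliper growth series,
    and DAB-like image tiles with known ground truth, so the full pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
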