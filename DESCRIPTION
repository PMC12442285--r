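Package: petagree
Title: Quantitative PET Biomarkers and Inter-Reader Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the quantitative FDG PET biomarkers metabolic tumour
    volume (MTV), total lesion glycolysis (TLG) and lesion dissemination
    distance (Dmax) from SUV volumes and binary lesion segmentations in
    NIfTI-1 format, and quantifies inter-reader agreement of these
    biomarkers between two independent readings: Spearman correlation with
    Fisher-z confidence intervals, Bland-Altman bias and limits of
    agreement, and median-split percentage agreement with Cohen's kappa,
    with an optional small-lesion (< 3 cm3) exclusion. Includes a
    deterministic synthetic phantom cohort generator that emulates
    two-reader segmentation disagreement (boundary jitter and inconsistent
    inclusion of small lesions) so the full pipeline can be exercised and
    tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
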