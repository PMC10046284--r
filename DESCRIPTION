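Package: dabquant
Title: Objective DAB Immunohistochemistry Scoring and Tumor-to-Background
    Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies DAB chromogen staining in brightfield histology
    tiles with an objective 5-step protocol: pathologist-annotated tumor
    and adjacent-healthy regions of interest, H-DAB color deconvolution,
    grayscale inversion, and per-region intensity statistics, yielding
    tumor-to-background ratios and cohort-level paired and unpaired
    t-tests for biomarker triage (e.g. for fluorescence-guided surgery).
    Includes a seeded Beer-Lambert phantom generator with per-biomarker
    cohort presets so the full pipeline can be verified against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
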