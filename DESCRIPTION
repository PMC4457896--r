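Package: csfstrat
Title: Stratification of Cerebrospinal Fluid 2-DE Proteomic Profiles
Version: 0.1.0
Authors@R:
    person("CSF Proteomics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for prognostic stratification of patients from
    two-dimensional gel electrophoresis (2-DE) spot quantification tables:
    percent-volume (%Vol) normalization, technical-replicate variability QC
    with best-pair selection, UPGMA hierarchical clustering of patient
    profiles under Euclidean distance, exact Mann-Whitney plus fold-change
    differential spot selection, linear discriminant classification functions
    over marker spots (vitamin D binding protein isoforms and apolipoprotein
    E), and cross-tabulation of proteomic clusters against clinical
    aggressiveness classes with predictive values and chi-square association.
    Includes a synthetic cohort generator with planted ground truth for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
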