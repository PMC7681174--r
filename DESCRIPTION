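Package: isrsa
Title: Intersubject Representational Similarity Analysis for Searchlight fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intersubject representational similarity analysis
    (IS-RSA) of multivoxel fMRI beta patterns. Builds trait-based
    intersubject dissimilarity models (Anna Karenina low-alike and
    high-alike models, nearest-neighbours models on summary scores or
    item-wise responses), computes subject-by-subject neural
    dissimilarity matrices (1 minus Spearman rho) within 100-voxel
    spherical searchlights, tests model-neural correspondence with Mantel
    permutation tests, and thresholds the resulting statistic maps with
    cluster-extent and false-discovery-rate rules. Includes scoring of
    two-informant trait questionnaires (highest-response combination,
    mean imputation), partial Spearman correlations for ROI analyses, and
    a synthetic cohort and beta-map generator with planted intersubject
    structure for validation and power analysis.
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
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
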