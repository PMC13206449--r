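Package: allomatch
Title: Evaluating Head-Size Adjustment Methods for Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation-backed framework for evaluating how total
    intracranial volume (TIV) adjustment methods affect standardized
    estimates of sex-differentiated aging trajectories in brain
    morphometry. Builds an exactly matched (age and TIV) gold-standard
    sample, applies the proportions, power-corrected proportions,
    residuals, and covariate adjustment methods, fits standardized
    per-unit trajectory models, and quantifies the residual bias of each
    method, including its spatial association with allometric scaling via
    a spin permutation test. Ships a synthetic cohort generator that
    emulates the statistical structure of large population imaging
    cohorts (sex-specific TIV distributions, power-law regional scaling,
    linear age decline), so every stage is testable without restricted
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, igraph, Matrix
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
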