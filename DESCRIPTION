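Package: cohmap
Title: Discourse Coherence Scoring and Lesion-Symptom Mapping for Aphasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes latent-semantic-analysis (LSA) based global coherence
    scores for discourse transcripts against control-derived prototype
    vectors, relates coherence to language and cognitive component scores
    through mixed ANOVA and staged regression models, and localizes lesion
    correlates of coherence deficits with univariate voxel-based
    correlational mapping (VBCM) and multivariate support-vector-regression
    lesion-symptom mapping (SVR-LSM), both with permutation-based
    cluster-level family-wise error control. Includes a synthetic cohort
    generator (transcripts, component scores, lesion volumes) with known
    ground truth so the full pipeline can be exercised and validated
    without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
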