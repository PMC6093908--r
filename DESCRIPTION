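Package: chemrank
Title: Target Deconvolution and Ranking for Chemical-Genetic Phenotypic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for annotated-library ("chemical genetic")
    phenotypic screens, built around a glucose-production assay in primary
    hepatocytes. Provides plate-level quality control (percent-of-control
    normalization, coefficient of variation, Z-prime factor), hit calling with
    cytotoxicity and detection-interference exclusion, a target-deconvolution
    statistic that scores each annotated protein target by the proportion of
    its compounds scoring positive penalized by the Wilson-interval width,
    combines active- and inactive-channel evidence across a balance-factor
    sweep, and ranks targets by the area under the rank-versus-balance curve.
    Also includes delta-delta-Ct quantification for follow-up qPCR arrays and
    a fully deterministic synthetic-screen generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
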