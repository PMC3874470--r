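Package: episcreen
Title: Two-Stage Screening-Testing for Gene-Gene and Gene-Environment
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the two-stage screening-testing framework for
    detecting gene-gene (GxG) and gene-environment (GxE) interactions in
    case-control data. Feature pairs are first screened with a
    disease-independent statistic, the composite linkage disequilibrium
    between additively coded genotypes measured by Pearson's product-moment
    correlation, and only pairs surviving the screen are formally tested in
    a logistic (or, for continuous traits, linear) regression model with an
    interaction term, with multiplicity correction counting only the tests
    actually conducted. Includes a plug-in permutation estimator of the
    false discovery rate usable with very few permutations, a fully
    parameterized simulator of case-control data under a log relative-risk
    penetrance model, and scripted power and calibration studies showing
    that main effects boost pooled-sample screening power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
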