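Package: netmorph
Title: Network-Guided Analysis of Cortical Morphometry and Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating vertex-wise cortical morphometry (thickness,
    surface area) to cognitive abilities in older adults, organised by a
    7-network functional parcellation. Builds composite cognitive scores from
    a task battery (winsorization, PCA with varimax rotation, averaging of
    standardized member tasks); fits cross-validated select-average-regress
    predictive models per network (robust scaling, univariate p-threshold
    vertex selection, one-coefficient linear models averaged over repeated
    5-fold partitions); performs bootstrap inference on partial correlations
    and difference-of-coefficients mediation of the age-cognition
    relationship; and maps vertex-wise bootstrap ratios with per-network
    suprathreshold counts tested against a permutation (shuffled-label) null.
    Includes a synthetic-cohort generator that emulates the statistical
    structure of an aging-cohort morphometry study so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
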