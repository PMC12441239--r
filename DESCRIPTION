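Package: standcarbon
Title: Stand Structural Diversity and Forest Carbon Pool Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying forest stand structure from mapped stem
    data and relating it to ecosystem carbon storage. Computes
    nearest-neighbour spatial structural diversity indices (uniform angle,
    dominance, mingling, crowding) and diameter-based non-spatial diversity
    (coefficient of variation, skewness, Gini coefficient of basal area,
    Shannon diameter-class diversity), converts field measurements to carbon
    pools (tree allometry, understory and litter harvests, soil stock
    equation), classifies plots into structural types by principal component
    analysis with Ward clustering, and tests structure-carbon associations
    with permutation Mantel tests. Includes a synthetic stand generator
    (Poisson, Thomas cluster, and jittered-lattice point processes with
    diameter and species marks) so the full analysis pipeline can be
    exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
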