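Package: chemodev
Title: Personalized Chemoresistance Gene Detection via Expression Deviation Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose expression in drug-resistant tumour samples
    deviates from the "normal range" defined by chemotherapy-sensitive
    samples, using a clamped cumulative deviation score tested by label
    permutation. Downstream stages cluster patients into molecular
    subgroups (median centering, centred Pearson correlation, average
    linkage), allocate significant genes to subgroups by fluctuation-range
    comparison, score pathway-level deviation, perform hypergeometric
    gene-set enrichment with Benjamini-Hochberg correction, rank hub
    biomarkers by degree in a restricted protein-interaction network, and
    validate biomarker panels with a decision tree trained on ternary
    (mean +/- sd) discretized expression. A seeded synthetic-cohort
    generator with planted ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    igraph,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
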