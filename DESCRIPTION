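Package: tomonet
Title: Perceptual Tomography of Social Networks from Third-Party Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed perceived social networks and perceived individual
    attributes from third-party photo-binning survey reports. Respondents sort
    a random subset of a photographed population roster into close / recognized
    / unknown bins, cluster the recognized members, and give binary opinions on
    community attributes. A blind-respondent null model yields exact binomial
    significance thresholds for co-clustering counts, from which positive ties
    and "robust intransitive" (perceived non-) ties are ascribed; perceived
    attributes are ascribed by exact one-sided binomial tests; the signed
    network is partitioned by a structural-balance criterion with a relocation
    heuristic validated against an exhaustive oracle; class-attribute
    associations are tested by multinomial logistic regression. A fully seeded
    synthetic-report simulator (null and planted-community regimes) supports
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    nnet,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
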