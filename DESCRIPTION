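Package: focalsna
Title: Social Network Analysis of Focal-Sampling Observation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds directed, weighted social networks from focal-sampling
    observation data (nearest-neighbour scans and timed dyadic interactions)
    using a Simple Ratio Index with a structurally zero joint-absence term,
    and analyses them with the toolkit used in captive-colony behavioural
    studies: binomial mixture modelling of dyadic association with
    integrated-completed-likelihood (ICL) model selection and Shannon-entropy
    social complexity, weighted assortment with node-label permutation tests,
    MRQAP network regression with Dekker double-semi-partialling, David's
    score dominance ranking with hierarchy linearity testing, node-metric
    social-role models with permutation-null coefficient inference, and QAP
    temporal-stability tests. Includes a synthetic focal-sampling data
    generator with planted social structure for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
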