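Package: spornet
Title: Outcome-Weighted Shared-Patient Collaboration Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds healthcare provider collaboration networks from
    encounter-level event records. Binary encounter outcomes are
    risk-adjusted with a logistic regression model, the bipartite
    provider-encounter network is projected onto provider pairs above a
    shared-encounter threshold, and every edge is weighted with the Shared
    Positive Outcome Ratio (SPOR): the ratio of the Shared Positive Outcome
    Index (risk-adjusted outcome mass concentrated in shared encounters) to
    the Shared Encounter Index (Jaccard overlap of the two providers'
    encounter sets). Edges are assessed against an outcome-permutation null
    model, classified as high- or low-scoring, and summarised into provider
    scoring groups. A synthetic encounter generator with pooled provider
    teams, acuity-driven outcomes and optional enriched pairs supports
    calibration and power analysis without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
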