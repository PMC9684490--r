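Package: grncf
Title: Gene Regulatory Network Inference by Collaborative Filtering and
    Sparse Network Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers weighted gene regulatory networks by jointly fitting a
    confidence-weighted collaborative-filtering model over incomplete prior
    TF-gene networks and a sparse network-component-analysis model of gene
    expression. The coupled non-convex objective, which contains an l0 edge
    penalty inseparable from the latent factors, is minimized by a
    generalized proximal alternating linearized scheme with closed-form
    activity updates, elementwise hard thresholding of the network, and
    unit-ball-constrained quadratic subproblems for the latent features.
    Includes percentile-based Average Rank Score benchmarking against a
    gold standard, PriorSum and random baselines, gold-standard
    construction from differential-expression tables, a Pearson
    co-expression prior builder, and a seeded simulator of planted
    networks, TF activities, expression, and degraded priors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
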