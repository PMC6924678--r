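Package: nichesim
Title: Virtual Communities for Benchmarking Niche-Model-Based Conservation Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for quantifying when ecological niche model
    (ENM) based conservation prioritization outperforms prioritization from
    raw survey records. Generates virtual presence/absence communities on a
    one-dimensional environmental gradient under preset rank-abundance curves,
    richness patterns and unimodal environmental preferences; simulates
    spatially biased surveys with a block design; fits per-species niche
    models (quadratic-logit GLM, spline GAM, random forest); selects reserve
    networks of fixed size by greedy complementarity, either on observed
    records or by maximizing the expected number of species represented; and
    evaluates both approaches against the known true distributions with an
    effectiveness index over full factorial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    mgcv,
    ranger,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Ecology, StatisticalMethod
RoxygenNote: 7.3.3
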