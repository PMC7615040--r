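Package: bnsdm
Title: Species Distribution Ensembles Refined by Bayesian Networks of
    Biotic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An ensemble species distribution modelling (SDM) pipeline in
    which per-cell habitat-suitability priors from climate-envelope,
    logistic-regression and random-forest models are modified by a Bayesian
    network of signed biotic interactions (food plants, predators,
    competitors), then thresholded with the True Skill Statistic or a
    prevalence rule and summarised as habitat area, patch density and
    percent change under present and future climate scenarios. A virtual
    ecosystem generator (autocorrelated bioclimatic grids, Gaussian-niche
    virtual species, contaminated occurrence samples) exercises every stage
    at desk scale, and all stages accept user data in plain CSV and ESRI
    ASCII grid formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    glmnet,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
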