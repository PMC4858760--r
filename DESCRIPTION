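Package: mossgrad
Title: Latitudinal Diversity Gradients on Gridded Landscapes via Stacked
    Species Distribution Models and Beta-Diversity Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and dissecting latitudinal diversity
    gradients on equal-area gridded landscapes. Occurrence records are
    rasterized to a presence/absence lattice, modelled per species with an
    ensemble of distribution models (logistic regression, random forests
    and a presence/background weighted logistic model) under replicated
    split-sample evaluation, binarized by threshold consensus and stacked
    into potential species richness maps. Compositional structure is
    analysed with the multiple-site Sorensen dissimilarity partitioned
    into turnover and nestedness-resultant components, compared between
    regions by resampling; spatial association between richness maps is
    measured with global and local Lee's L statistics with Monte Carlo
    significance; richness is profiled in latitudinal bands with
    species-area normalization. A synthetic-community generator with
    controlled nestedness/turnover architecture provides ground truth for
    the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
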