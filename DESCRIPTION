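Package: etibdiv
Title: Diversity-Trend Inference from Metabarcoding Time Series Under an
    Island-Biogeography Null Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of multidecadal biodiversity change from
    OTU-by-sample metabarcoding time series, such as those obtained from
    archived natural-sampler organisms. Provides dataset filtering and
    presence/absence conversion, alpha/beta/gamma diversity indices
    (Jaccard dissimilarity and its turnover component, bootstrap regional
    richness, ACE), a non-neutral dynamic occupancy model derived from the
    equilibrium theory of island biogeography with imperfect detection,
    sequential parameter inference (ACE detection probability, hidden
    Markov maximum likelihood for immigration and extinction rates,
    simulation-based inference with a neural regressor for metacommunity
    size and non-neutrality), AR(1) mixed-model trend estimation,
    null-ensemble significance tests, the delta-alpha versus delta-gamma
    homogenization-differentiation classification, per-OTU occurrence
    trends, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
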