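Package: geomstate
Title: State-Space Geometry of Working-Memory Task Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying low-dimensional task-congruent geometry in
    neural population data. Implements the circularity index of
    PCA-projected condition polygons, time-resolved estimation with
    stratified resampling, cluster-based permutation inference,
    behavioral trial-split contrasts, representational similarity
    analysis with 2D and conjunctive goal models, theta-band
    weighted phase-lag index coherence, and a volumetric searchlight
    with group-level bootstrap cluster correction. A synthetic-data
    generator plants known goal and stimulus geometries into
    multichannel epochs and trial-wise beta volumes so every stage
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
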