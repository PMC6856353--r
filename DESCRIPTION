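Package: twinmap
Title: Whole-Cortex Genetic Mapping of Brain-Behavior Covariance in Twin Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise bivariate twin ACE/AE Cholesky models fitted by
    full-information maximum likelihood, decomposing the covariance between
    cortical thickness and behavioral phenotypes into additive genetic,
    shared environmental, and non-shared environmental parts. Builds
    per-vertex maps of bivariate heritability and environmentality with
    likelihood-ratio significance tests, applies cluster-extent correction on
    triangulated surface meshes, overlays genetic clusters across traits
    (conjunction), runs family-preserving split-half replication, and
    clusters gene-by-region expression matrices by k-means with elbow model
    selection. Includes synthetic twin-cohort, mesh, and expression
    generators with known ground truth, and readers/writers for FreeSurfer
    curv/MGH, binary surface, GIFTI, and delimited-text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    xml2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
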