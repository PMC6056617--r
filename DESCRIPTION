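Package: fcdmapr
Title: Functional Connectivity Density Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise functional connectivity density (FCD) analysis of
    resting-state BOLD fMRI. Computes global, short-range (local, via a
    correlation-thresholded growing algorithm) and long-range FCD maps,
    performs covariate-adjusted voxel-wise group comparison with Monte-Carlo
    cluster-extent correction, seed-based follow-up connectivity with Fisher
    r-to-z, and partial-correlation analysis of cluster-mean FCD against
    clinical scores. Includes a synthetic-cohort generator with planted
    short- and long-range connectivity structure so the whole pipeline can
    be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
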