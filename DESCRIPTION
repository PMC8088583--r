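Package: essdyn
Title: Essential Dynamics Analysis of Molecular Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for essential dynamics analysis of molecular
    conformational ensembles read from multi-frame PDB data. Builds
    covariance, correlation and partial-correlation models with rare-event
    and adaptive covariance shrinkage and eigenvalue floor conditioning;
    performs Cartesian, distance-pair, hierarchical and kernel principal
    component analysis; scores residue-residue dynamical coupling from
    mode-coupling covariance matrices; filters rare events into inlier and
    outlier ensembles; sparsifies statistical matrices; and compares
    essential subspaces with RMSIP, cumulative overlap, principal angles
    and random-basis baselines. Includes a synthetic-ensemble generator
    with planted covariance modes for validation, and free-energy surfaces
    from the top two projections.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
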