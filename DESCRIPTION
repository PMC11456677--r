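Package: cbtcloops
Title: Individual-Level Cortico-Basal Ganglia-Thalamo-Cortical Circuit
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity
    within the parallel cortico-basal ganglia-thalamo-cortical (CBTC)
    loops: connectivity-profile-based (winner-take-all) parcellation of
    subcortical structures into cortically defined subdivisions,
    edge-wise Fisher-z functional connectivity extraction for the
    loop-structured and whole-structure (atlas) edge sets, edge-wise
    group comparison with FDR correction, F-score-ranked linear
    support-vector-machine case-control classification with
    leave-one-out cross-validation and permutation inference, and
    connectome-based predictive modelling of upper-limb motor scores.
    Includes a seeded synthetic-cohort generator (loop-structured region
    covariance, planted group effects, behaviour coupled to designated
    edges, and Dirichlet voxel connectivity profiles) so that every
    stage is testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
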