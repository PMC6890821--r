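Package: dynpocket
Title: Trajectory Flexibility Metrics, Essential Dynamics, and
    Druggable-Pocket Classification for Kinase Ensembles
Version: 0.1.0
Authors@R:
    person("dynpocket", "developers", email = "dynpocket@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics ensembles of two-lobe
    protein kinases such as p38alpha (MAPK14). Reads multi-model PDB and DCD
    trajectories; computes Kabsch superpositions, RMSD time series,
    all-to-all RMSD convergence matrices, and per-residue RMSF profiles;
    performs essential-dynamics PCA of Calpha covariance with projections,
    extreme structures, and morphing; compares simulated ensembles against
    experimental NMR chemical shifts and residual dipolar couplings by
    linear regression with outlier ranking; and classifies solvent-mapping
    probe clusters into named binding pockets by bounding-sphere
    intersection volumes, aggregating consensus strength to call
    druggability. Seeded synthetic generators (two-domain hinge/twist
    ensembles, planted probe clusters, observable tables) provide ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
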