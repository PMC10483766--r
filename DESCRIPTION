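Package: afosim
Title: Predictive Neuromusculoskeletal Simulation of Walking with
    Ankle-Foot Orthoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Planar reflex-controlled neuromusculoskeletal walking
    simulation for studying dorsal-leaf ankle-foot orthoses (AFOs) in
    bilateral plantarflexor weakness.  Provides a seven-segment,
    nine-degree-of-freedom forward-dynamic gait model with Hill-type
    muscle-tendon units, Hunt-Crossley foot-ground contact, a
    gait-phase-dependent reflex controller optimized by CMA-ES, and a
    muscle energetics model; model variants with graded plantarflexor
    weakness, altered passive muscle stiffness, added body mass and
    enforced walking speed; AFO stiffness sweeps with cubic-response
    extraction of the energy-optimal stiffness and of the minimum
    stiffness normalizing gait parameters; and gait validation metrics
    (cycle segmentation, time normalization, cross-correlation,
    SD-normalized RMSE, one-dimensional statistical parametric mapping).
    A synthetic-data module generates reference gait bands, noisy cycle
    cohorts and energy-stiffness response tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
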