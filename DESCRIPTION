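Package: crstab
Title: Structural Sensitivity of Consumer-Resource Models in Equilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how the choice of functional response
    terms shapes the local stability of consumer-resource equilibria.
    Implements the Lotka-Volterra (LV), Lotka-Volterra-Verhulst (LVV),
    Rosenzweig-MacArthur (RM) and Rosenzweig-MacArthur-Scheffer (RMS)
    models, their equilibrium-preserving linearized counterparts, analytic
    Jacobians with eigenvalue-based regime classification, and sweeps
    along environmental gradients (carrying capacity K, top-consumer
    pressure F) that detect transcritical, Hopf, fold and homoclinic
    bifurcations.  A virtual-sampling stage treats model equilibria as
    field observations of biomasses and material fluxes and fits
    Lotka-Volterra-type models to them, emulating the construction of
    empirical food web models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
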