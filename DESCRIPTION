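Package: rpbpk
Title: Reduced Brain PBPK Modelling of Antibody Uptake into CSF and Brain ISF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for a reduced physiologically-based
    pharmacokinetic (rPBPK) model of monoclonal-antibody disposition in the rat
    central nervous system. The model tracks 13 amounts (plasma, lymph, a lumped
    rest-of-body tissue with an FcRn-bearing endosomal space, brain vasculature,
    four cerebrospinal-fluid sub-compartments and brain interstitial fluid) and
    describes brain uptake as convection across the blood-brain and blood-CSF
    barriers governed by drug-specific reflection coefficients. Includes a stiff
    Rosenbrock ODE integrator, intravenous and intracerebroventricular dose
    arithmetic, two-stage naive-pooled nonlinear least-squares estimation with
    logit-transformed reflection coefficients, non-compartmental analysis,
    microdialysis recovery correction, pathway (source-apportionment) analysis,
    a study-design-faithful synthetic data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
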