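Package: bayeslss
Title: Bayesian Limited Sampling Strategies for Cyclosporine AUC Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic simulation and estimation toolkit for
    developing Bayesian limited sampling strategies (B-LSS) that predict the
    cyclosporine area under the concentration-time curve (AUC 0-12 h) in
    pediatric hematopoietic stem cell transplantation. Provides analytic one-
    and two-compartment steady-state concentration models with absorption lag
    time and zero-order infusion, nonlinear mixed-effects population fitting by
    a Laplace-approximated marginal likelihood, empirical-Bayes MAP estimation
    of individual parameters, exhaustive enumeration of limited sampling
    designs with leave-one-out cross-validated AUC prediction-error indices, a
    virtual pediatric cohort generator, and publication-shaped reporting of
    design performance against observed and underlying (residual-error-free)
    AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
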