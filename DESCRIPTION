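Package: treopk
Title: Population Pharmacokinetics and Limited Sampling Strategies for
    Treosulfan in Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of treosulfan
    given as intravenous infusion before hematopoietic stem cell
    transplantation in pediatric patients.  Implements an analytic
    two-compartment infusion model with allometric bodyweight scaling,
    log-normal interindividual variability and proportional residual
    error; a virtual pediatric cohort simulator; non-compartmental
    AUC estimation by the linear-up/log-down rule; development and
    validation of two- and three-point limited sampling strategies by
    multiple regression and by Bayesian maximum a posteriori estimation;
    nonlinear mixed-effects fitting of the population model with
    likelihood-ratio model comparison, eta-shrinkage, nonparametric
    bootstrap and prediction-corrected visual predictive checks; and the
    Sheiner-Beal prediction-error metrics used to score exposure
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
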