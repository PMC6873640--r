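Package: shockvec
Title: Whole-Torso Simulation of Defibrillation Fields and the Shock Vector
    Efficiency Metric
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates parameterized synthetic whole-torso voxel phantoms with
    implantable cardioverter-defibrillator (ICD) electrode configurations,
    solves the anisotropic extracellular potential problem (Laplace and
    passive elliptic-parabolic bidomain formulations) on the voxel grid, and
    computes defibrillation efficacy metrics: the 95%/5 V/cm defibrillation
    threshold surrogate, pathway impedance from constant-current injection,
    and the shock vector efficiency (the fraction of Joule-dissipated shock
    energy deposited in ventricular myocardium relative to the whole torso).
    Includes rule-based myocardial fibre generation from Laplace-Dirichlet
    scalar fields, hypertrophic and dilated cardiomyopathy geometry variants,
    and experiment drivers for cohort sweeps, solver-mode comparison, and
    torso-height convergence studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    ggplot2,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
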