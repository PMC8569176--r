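Package: wusgrad
Title: Cell-Based Modelling of WUSCHEL Gradient Robustness in the Shoot
    Apical Meristem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D cell-based reaction-diffusion model of the
    WUSCHEL-CLAVATA3 feedback in the shoot apical meristem with
    nuclear-cytoplasmic partitioning of the WUS transcription factor.
    Provides a deterministic layered cell template generator, graph
    diffusion on cell-cell contacts, a TVD-RK2 tissue integrator, the
    reduced single-compartment ODE system with steady-state and linear
    stability analysis, global (Sobol' total-effect) and local (Latin
    hypercube + partial correlation) sensitivity analyses, parameter-set
    screening against gradient selection criteria, and perturbation
    sweeps comparing transcriptional-only, dual, and dual-plus-spatial
    CLV3 regulation of the WUS gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
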