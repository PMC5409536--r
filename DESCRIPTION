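Package: ligandsense
Title: Multi-Ligand Concentration Inference from Single-Receptor Binding Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the concentrations of two ligand species (a cognate
    and a faster-unbinding non-cognate competitor) from the stochastic
    sequence of binding and unbinding intervals observed on a single
    receptor. Provides exact maximum-likelihood inference with
    Hessian-based (Cramer-Rao) error estimates, a biochemically plausible
    long-event threshold estimator with analytic bias, variance and
    bias-variance-optimal cutoff, two kinetic-proofreading readout
    schemes (incoherent feedforward subtraction and activator-inhibitor
    sequestration with ligand antagonism), an exact stochastic simulator
    of receptor occupancy traces and trace-driven messenger birth-death
    processes, and orchestration of replicate simulation sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
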