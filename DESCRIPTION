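Package: mrafit
Title: Fit ODE Models of Signalling Networks to Steady-State Perturbation
    Data via Modular Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates ordinary differential equation models of signal
    transduction networks against steady-state perturbation response data
    without simulating the perturbation experiments. Local response
    coefficients (the scaled Jacobian of the network) are estimated from
    perturbation data by modular response analysis and computed for any
    candidate parameter set by differentiating the model's rate equations at
    its unperturbed steady state; the two are matched inside an
    adaptive-weight approximate Bayesian computation sequential Monte Carlo
    sampler. Ships Michaelis-Menten models of the MAPK/ERK cascade under EGF
    and under EGF/NGF stimulation, an in-silico siRNA perturbation experiment
    generator, and posterior-predictive tools (dose-response curves, ligand
    wash-out time courses, and cell-population modality analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 3.5.0)
Imports:
    deSolve,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
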