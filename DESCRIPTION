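Package: crmrept
Title: Convection-Reaction MR Electrical Properties Tomography of Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for high-frequency
    conductivity imaging of brain tumors at ultra-high field. Generates
    multi-coil multi-echo spin-echo phantom data over piecewise
    conductivity/diffusivity phantoms, combines receive-channel phases with a
    referenceless two-step scheme, unwraps and echo-averages the transceive B1
    phase, reconstructs conductivity maps both by the phase-based Laplacian
    estimate and by solving the stabilized convection-reaction equation for
    1/sigma with sparse finite differences, fits diffusion tensors for mean
    diffusivity, and summarises parametric maps over volumes of interest with
    Welch t-tests and Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
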