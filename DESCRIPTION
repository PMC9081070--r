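Package: cztcam
Title: Charge-Induction and Energy-Response Modelling for Pixelated CZT
    Gamma Cameras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the energy response of pixelated cadmium zinc
    telluride (CZT) gamma-camera modules. Solves the three-dimensional
    electric and Shockley-Ramo weighting potentials on a finite-difference
    grid, computes charge-induction-efficiency (CIE) maps with a
    steady-state adjoint drift-diffusion solver (with Hecht-equation and
    direct time-stepping oracles), synthesises photon-interaction listmode
    streams as a stand-in for an external Monte Carlo transport code,
    converts histories into per-anode energy spectra and images through a
    winning-anode detector model with linear energy calibration and
    energy-dependent Gaussian resolution, and tunes CIE and resolution
    parameters against reference spectra with a nested downhill-simplex
    procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
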