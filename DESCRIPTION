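Package: crtsim
Title: Continuum Multiphase Simulation of Vascular Tumor Growth Under
    Chemo-Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of a vascularised tumor inside a host
    tissue treated as a multiphase mixture of healthy cells, cancer cells,
    young and mature blood vessels and interstitial fluid, coupled to
    quasi-steady reaction-diffusion fields for oxygen, vascular endothelial
    growth factor (VEGF), bevacizumab and docetaxel.  Treatment forcing
    covers fractionated external-beam radiotherapy with linear-quadratic
    calibration utilities, pulsed intravenous pharmacokinetics for the
    anti-VEGF and cytotoxic agents, and docetaxel- or oxygen-driven
    radiosensitization.  The coupled system is discretised with finite
    volumes on a radially symmetric grid and advanced with a segregated
    implicit (BDF2) scheme; tumor burden is reported as surface coverage,
    tumor radius and healthy-tissue recession.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
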