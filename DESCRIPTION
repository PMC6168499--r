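Package: gradspheroid
Title: Self-Generated Microfluidic Drug-Gradient Spheroid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a pumpless microfluidic drug screen on
    multicellular tumour spheroids. Models the device's hydrostatic
    pressure-driven flow as a resistive-capacitive hydraulic network
    (including overflow-port clamping), simulates the self-generated
    compound concentration gradient over the micro-well array with a
    depth-averaged advection-diffusion solver, generates ground-truthed
    synthetic brightfield/FDA/PI image sets of spheroid arrays, extracts
    image-based health readouts (shape factor, viable fraction), and fits
    8-point concentration-response curves with EC50 estimation and
    shape-factor/viable-fraction correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
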