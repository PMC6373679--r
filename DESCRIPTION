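Package: abebnct
Title: Absolute Biological Effectiveness Dosimetry for Boron Neutron
    Capture Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the cell-killing effect of the boron-neutron
    dose in boron neutron capture therapy (BNCT). Fits exponential clonogenic
    survival curves against thermal neutron fluence, isolates the
    10B(n,alpha)7Li component by slope subtraction to obtain phi0 and D0,
    computes nucleocytoplasmic ratio and cell-size index from H&E-style
    histology rasters with a stereological cell/nucleus diameter estimate,
    fits the predictive regressions linking morphometry to D0 (power law on
    the N/C ratio for BPA, linear on the cell-size index for BSH), and
    converts physical doses to absolute biological effectiveness (ABE) doses.
    Includes seed-deterministic generators for simulated colony-survival
    experiments, rendered tissue sections with ground-truth masks, and
    Monte-Carlo sphere-sectioning geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
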