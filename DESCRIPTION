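Package: emval
Title: Validation of 3D Electron Microscopy Maps and Atomic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for assessing the quality of three-dimensional electron
    microscopy (3DEM) reconstructions and the atomic models fitted into them.
    Reads and writes CCP4/MRC-style density maps; computes Fourier Shell
    Correlation (FSC) between independent half-maps and estimates resolution
    under the common fixed-value, half-bit and three-sigma threshold criteria;
    produces single-map summary statistics (density histogram, rotationally
    averaged power spectrum, enclosed volume versus contour level, orthogonal
    projections and central slices); validates trace-only coordinate models
    (C-alpha-only protein chains, P-only nucleic acid chains) via consecutive
    trace-bond distance checks, pseudo-Ramachandran analysis and close
    contacts; scores model atom inclusion in density at a contour level; and
    assembles the results into a machine-readable validation report with
    percentile indicators against reference populations. Includes seeded
    synthetic generators (Gaussian-atom maps, half-map pairs with designed
    signal-to-noise profiles, ideal and perturbed traces) for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    xml2,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
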