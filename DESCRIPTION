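Package: microbeam
Title: Mechanics of 3D-Bioprinted Cell-ECM Microbeams in Packed Microgel Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the mechanical fate of 3D-bioprinted microbeams made from
    cells and extracellular matrix embedded in packed-microgel support media.
    Implements Euler-Bernoulli buckling of a beam on an elastic foundation
    (wavelength, critical force and stress), an energy-balance failure model
    against the medium yield stress, the axial-contraction force balance,
    rule-based classification of beam fate on a stability diagram, estimation
    of stability-diagram thresholds from outcome cohorts, single-cell
    contractile stress estimators at instability thresholds, and recovery of
    the power-law scaling of cell stress with matrix modulus. Includes a
    seeded virtual-experiment generator producing beam cohorts and sampled
    centerlines, spectral and real-space wavelength measurement, and an
    end-to-end pipeline with a JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
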