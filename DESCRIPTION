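Package: betadose
Title: Cumulative Surface Beta-Ray Dose from Radionuclide Fallout Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the cumulative one-year beta-ray dose (70 micrometre
    dose equivalent) on the ground surface after a large radionuclide
    deposition event. Implements a seven-nuclide decay and surface dose-rate
    model driven by two deposition-ratio parameters (I-131/Cs-137 and
    Te-129m/Cs-137), its exact reduction to a linear dose surface, decay
    correction of measured activity ratios to the deposition date,
    multilevel B-spline approximation of scattered ratio and dose fields
    onto regular grids, an end-to-end survey pipeline from activity tables
    to per-location doses and dose maps, and a synthetic deposition-survey
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
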