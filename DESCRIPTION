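Package: protonRBE
Title: Dose-Averaged LET and Variable RBE Analysis for Proton Therapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing proton-therapy dose distributions with
    dose-averaged linear energy transfer (LET) and variable relative
    biological effectiveness (RBE). Implements per-beam LET combination by
    relative-dose weighting, dose thresholding of LET maps, the McNamara
    linear-quadratic variable-RBE model alongside the clinical fixed RBE of
    1.1, and the standard plan-comparison metrics (cumulative DVHs, mean and
    near-maximum D0.1cc dose and LET, VxGy, CTV coverage, voxel-wise dose
    difference maps and high-dose/high-LET overlap volumes). Includes an
    analytical water-phantom beam simulator (pristine Bragg curves, spread-out
    Bragg peaks, depth-LET curves) that generates per-beam dose and LET grids
    for mediastinal-style plans with one to three coplanar fields, a portable
    text grid format, and a minimal DICOM RT Dose import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
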