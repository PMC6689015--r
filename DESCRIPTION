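Package: cine5d
Title: Cardiorespiratory-Resolved 3D Cine MRI Simulation, Reconstruction and
    Ventricular Function Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for respiratory-resolved 3D cardiac cine MRI
    ("5D" imaging: x-y-z-cardiac-respiratory). Includes a digital
    cardiorespiratory phantom and multi-coil k-space simulator with known
    ground truth; CIRCUS pseudo-random variable-density Cartesian
    undersampling with partial Fourier; ECG-synchronised per-heartbeat sorting
    with view sharing and low-resolution beat volumes; absolute 3D respiratory
    motion tracking by multi-resolution demons registration; k-means binning
    of heartbeats into four respiratory phases with end-expiration /
    end-inspiration identification and respiratory metrics; compressed-sensing
    reconstruction (k-t SPARSE-SENSE with cardiac temporal total variation);
    and left/right ventricular volumetry (ESV, EDV, SV, EF) via Hough-circle
    initialisation and elliptically refined level-set segmentation, with the
    paired statistics used to compare respiratory phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
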