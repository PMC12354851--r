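Package: alphamap
Title: Quantitative Alpha-Particle Autoradiography, Histology Integration and
    Microscale Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quantitative digital alpha-particle autoradiography
    and microscale dosimetry of alpha-emitter radiopharmaceutical therapy.
    Converts list-mode detection events to calibrated activity maps (Bq per
    pixel at a chosen reference time) with full radioactive-decay accounting
    across multiple acquisition sessions; fits the camera sensitivity factor
    and detector efficiency from dilution-series standards; estimates and
    corrects geometric detector distortion from calibration phantoms with
    Jacobian-determinant intensity preservation; co-registers stained-section
    histology to autoradiography under a multi-section rigid constraint;
    stacks serial sections into 3D activity volumes (activity-only or
    anatomy-guided); segments renal tissue, blood vessels and glomeruli and
    profiles uptake versus Euclidean distance from each compartment with
    replicate confidence intervals; and computes dose-rate maps by convolving
    a Monte-Carlo alpha dose-voxel kernel with the activity volume, with
    cumulative dose-volume histograms. Synthetic-data generators with known
    ground truth support validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    jsonlite,
    tiff,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
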