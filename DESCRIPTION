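Package: voxelus
Title: Voxel-Level Analysis of Functional Ultrasound Time Series
Version: 0.1.0
Authors@R: person("Voxelus", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing trial-based functional ultrasound (fUS)
    power-Doppler imaging data at single-voxel resolution. Implements the
    three standard analysis strategies for stimulus-evoked hemodynamic
    responses: region-based averaging with contrast-response curves,
    Pearson-correlation activation mapping with Fisher-transform
    significance thresholding, and single-voxel spatiotemporal clustering
    (PCA feature reduction, elbow-based cluster-count selection,
    multi-initialization K-Means with amplitude-ordered labels, and
    cluster-map stability scoring). Six hemodynamic-response metrics
    (peak amplitude, AUC by Simpson's rule, time to peak, response length,
    FWHM, time to half-maximum) are computed per trace with an optional
    zero-phase Butterworth low-pass prefilter. A synthetic microDoppler
    generator with planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
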