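Package: fastvolscan
Title: Simulation and Analysis of Fast Volume-Scanning Light-Sheet Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An in-silico model of fast volume-scanning light-sheet
    fluorescence microscopy for dendritic calcium imaging, together with the
    downstream transient-detection analysis. A synthetic dendrite phantom with
    ground-truth calcium events is imaged by an optical forward model in which
    a sine-swept light sheet and a synchronously swept detection focal plane
    integrate one full Z sweep per camera exposure, producing an average
    intensity projection per frame. The analysis side extracts ROI traces from
    XYT stacks, corrects photobleaching with an exponential background fit,
    computes dF/F, fits a rise/decay (alpha) function to candidate transients,
    and accepts events whose fitted amplitude exceeds the RMS noise of the
    preceding baseline. Includes phase calibration of the focal-plane drive
    against a bead phantom and recovery scoring against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
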