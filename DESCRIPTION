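Package: parmoco
Title: Partial-Angle Motion-Compensated Fan-Beam CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for cardiac motion
    correction in fan-beam computed tomography from less than one gantry
    rotation of data. Provides an ECG-driven dynamic analytic phantom with
    presets emulating a beating heart (contracting myocardial wall, chambers,
    coronary-artery-like disks) and moving coronary-artery phantoms; analytic
    time-resolved fan-beam forward projection; fan-to-parallel rebinning and
    short-scan weighted filtered backprojection; conjugate partial-angle
    reconstruction (PAR); band-pass edge extraction and multi-resolution cubic
    B-spline free-form-deformation registration between the conjugate PAR
    images; linear-in-time scaling of the estimated motion field and
    motion-compensated backprojection; and an evaluation suite (ROI-wise mean
    structural similarity, sub-region RMSE, HU line-profile stability, paired
    t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite,
    RNifti,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
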