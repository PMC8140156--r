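Package: rtlv
Title: Left Ventricular Function from Real-Time and Cine Short-Axis Cardiac MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of left-ventricular function from dynamic
    short-axis cardiac MRI label-mask series: semi-automatic cardiorespiratory
    phase sorting of beat-by-beat real-time series from blood-pool and
    lung-liver signal-time curves, Simpson's-method-of-disks volumetry with
    basal/apical slice-inclusion rules and papillary-muscle handling, derived
    functional parameters (EDV, ESV, SV, EF, CO, wall and papillary mass), and
    test-retest / inter-observer / method-comparison agreement statistics
    (ICC, Bland-Altman limits of agreement, regression). Includes an analytic
    beating, artificially ventilated ventricle phantom that generates NIfTI
    mask series, signal traces and ground-truth tables for end-to-end
    validation, plus the acquisition arithmetic of radial real-time and
    segmented cine protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
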