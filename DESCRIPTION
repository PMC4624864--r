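Package: gctfm
Title: Traction Force Dynamics of Axonal Growth Cones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and statistical analysis of the traction stresses
    generated by advancing neuronal growth cones on soft elastic substrates.
    Provides Fourier-transform traction cytometry based on the Boussinesq
    half-space Green's function (bead-image preprocessing, drift correction,
    cross-correlation displacement measurement, regularized spectral
    inversion), stress-based growth-cone localization and trajectory
    filtering, co-moving-frame stress averaging, stress-peak detection and
    lifetime statistics, and autocorrelation / mean-squared-displacement
    analysis of axon tension fluctuations. Includes a fully ground-truthed
    synthetic growth-cone simulator so that every stage of the pipeline can
    be validated without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
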