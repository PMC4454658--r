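Package: stereoscan
Title: Multiview Photometric-Stereo Surface Reconstruction and Scanner
    Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a robotic multi-light 3D surface scanner
    for quantitative phenotyping of biological surfaces. Estimates per-pixel
    surface normals from image stacks acquired under many calibrated
    directional lights, with rank-based rejection of shadowed and specular
    observations; integrates normal fields into height fields by
    frequency-domain (Frankot-Chellappa) and Poisson solvers; fuses unbiased
    low-frequency geometry from multiview stereo with high-frequency
    photometric-stereo gradients through a screened-Poisson linear system;
    carves visual hulls from calibrated silhouettes; plans overlapping camera
    poses on parametric scanning envelopes; and implements the scanner's
    quality-control analytics (positional-repeatability shift estimation,
    no-reference blur metric and vibration-attenuation fitting, USAF-1951
    resolving power, depth-of-field and Nyquist feature-size calculators).
    A synthetic-scene generator renders calibrated test surfaces so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
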