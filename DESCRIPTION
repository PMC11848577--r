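Package: opelast
Title: Optical Multifrequency Time-Harmonic Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, encoding, decoding and inversion tools for optical
    multifrequency time-harmonic elastography (OMTHE). Simulates
    multifrequency shear-wave fields in heterogeneous two-dimensional media
    by finite differences with absorbing boundaries, encodes them as
    sub-pixel harmonic motion in synthetic speckle movies under a
    stroboscopic acquisition schedule, decodes complex harmonic
    displacement fields with harmonic optical flow (a Horn-Schunck variant
    restricted to a time-harmonic ansatz), and inverts them to shear-wave
    speed maps by multifrequency dual elasto-visco (MDEV) direct inversion
    with long-lag finite gradient schemes. Includes preprocessing
    (exposure merging, contrast-limited adaptive histogram equalization,
    rigid registration), quantitative metrics (modulus conversions,
    wavelet-based signal-to-noise estimation, wavelength profile fits) and
    an end-to-end reference pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
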