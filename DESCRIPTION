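Package: holoscat
Title: Bidirectional Scattering Holographic Microscopy Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of spatial-frequency-multiplexed
    off-axis holograms that carry forward-scattered (transmission) and
    backward-scattered (epi) channels on a single sensor frame.
    Reconstructs complex amplitudes per channel, refocuses them by
    angular-spectrum propagation, corrects interferometric phase drift,
    and forms scattering-field-amplitude (SA) images.  Includes a
    physics-based hologram simulator with a Poisson camera model,
    shot-noise-floor calibration, Mie-based particle characterization
    (refractive index and diameter from paired forward/backward
    cross-sections), temporal band-limited fluctuation mapping, and
    phase-derived dry-mass quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
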