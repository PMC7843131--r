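Package: rapmicro
Title: Random-Access Parallel Microscopy: Optics, Demultiplexing and
    Activity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core for random-access parallel (RAP)
    bright-field microscopy, in which a single camera at the focus of a
    large parabolic mirror images many spatially separated samples by
    switching illumination LEDs between frames. Implements the closed-form
    geometric optics of the off-axis image (chief-ray angle, anisotropic
    stretch, magnification, defocus span, depth of field, numerical
    aperture, diffraction-limited resolution), forward simulation and
    inverse rectification of the geometric distortion, LED acquisition
    scheduling with lossless stream demultiplexing, dye-free cardiac
    motion analysis (motion signal, ROI traces, activation maps,
    conduction velocity), Caenorhabditis elegans activity quantification
    with group comparison, a grid-contrast estimator of lateral PSF width,
    and a seeded synthetic-data generator so the whole pipeline is
    testable without the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
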