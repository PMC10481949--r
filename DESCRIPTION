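Package: megarray
Title: Minimum-Assumption Design of MEG Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing magnetoencephalography (MEG) sensor
    arrays under minimal assumptions about the neuronal sources.  Models
    the magnetic field in the sensor volume with a truncated vector
    spherical harmonics (signal space separation) expansion, quantifies an
    array by the worst-case factor with which sensor noise is amplified
    when the neuronal field component is interpolated anywhere in a
    helmet-shaped sampling volume, optimizes sensor positions and
    orientations by simulated annealing to minimize that factor, and
    validates designs independently with the Shannon channel information
    capacity under a random-dipole spherical-conductor source model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
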