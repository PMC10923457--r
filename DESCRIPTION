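Package: surgsmoke
Title: Surgical Smoke Dispersion in a Laminar-Flow Operating Theatre
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how the tip temperature of an electro-surgical knife shapes
    the dispersion of surgical smoke (waste gases, condensed tar droplets and
    non-viable particles) in a laminar-flow operating theatre. Provides
    empirical source-term calibration polynomials fitted to an in vitro power
    sweep, a synthetic power-sweep generator for validating the calibration, a
    structured-grid finite-volume steady RANS solver with the standard k-epsilon
    closure, buoyancy and multi-species passive transport (SIMPLEC
    pressure-velocity coupling), Lagrangian tracking of 2 micron droplets and
    particles with Schiller-Naumann drag, and exposure analysis: maximum smoke
    ascent height above the incision, flow-zone decomposition, nose-height
    concentration profiles and occupational threshold flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
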