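Package: dcpt
Title: Dynamically Collimated Proton Therapy Planning and Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale planning, optimization, delivery-file and dosimetric
    validation pipeline for dynamically collimated proton pencil beam scanning
    (PBS). Provides an analytical single-beamlet dose engine in water (power-law
    Bragg curve with range straggling, Highland multiple Coulomb scattering,
    range-shifter angular scatter, trimmer-edge collimation), cubic-target plan
    generation with divergence-matched trimmer positioning, nonnegative
    least-squares spot-weight optimization with coverage normalization and
    minimum-MU filtering, a plain-text PBS layer definition (PLD) writer/reader
    with trimmer motion sequences, detector simulators (ionization-chamber
    array with shifted-merge acquisition, radiochromic-film-like sampling,
    multilayer ionization chamber), and the dosimetric metrics used to
    characterize collimated fields: 80-20 lateral penumbra, SOBP range, width
    and flatness, 2D gamma analysis, surface dose-horn enhancement, and rigid
    2D registration of measured to simulated dose planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
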