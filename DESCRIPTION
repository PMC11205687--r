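Package: thermoredux
Title: Data Reduction for Combustion and Drop Calorimetry Thermochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces static-bomb combustion calorimetry experiments and
    high-temperature Calvet drop-microcalorimetry runs to standard molar
    enthalpies of formation in the liquid and gas phases at 298.15 K.
    Covers the full chain: corrected adiabatic temperature rise
    (Regnault-Pfaundler), isothermal-bomb-process energy, auxiliary-material
    and nitric-acid corrections, simplified standard-state corrections,
    benzoic-acid calibration, Hess-law derivation with CODATA reference
    enthalpies, and heat-capacity correction of drop-calorimetric
    vaporization enthalpies to the reference temperature. Includes a
    gas-phase estimation toolkit (Boltzmann conformer weighting, isodesmic
    reaction solving from computed absolute enthalpies, substitution
    increments, and a monomer/dimer vaporization cycle) and synthetic-data
    generators that emulate both instruments for end-to-end validation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
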