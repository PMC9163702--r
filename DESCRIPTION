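Package: origamimelt
Title: Thermal Denaturation Analysis of Guanidinium-Bound DNA Origami from
    Circular Dichroism Melting Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the thermal denaturation of DNA origami
    nanostructures in guanidinium salt solutions. Reads circular dichroism
    (CD) spectral series with photomultiplier high-tension (HT) voltage
    screening, extracts melting temperatures from the 260 nm hyperchromic
    shift by baseline normalisation, computes temperature-sensitivity (TS)
    maps over three-point temperature windows, decomposes spectral series
    into structural-state components by constrained iterative target
    transformation factor analysis (ITTFA) anchored to AFM intact fractions
    and the ssDNA fraction, and fits a heat-capacity-aware four-state
    Boltzmann model (states S1, S2, S2', S3) to the resulting concentration
    profiles. A seeded synthetic-data generator emulates the acquisition
    grid and noise structure of the experiments so the whole chain is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
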