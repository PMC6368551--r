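Package: brinetrace
Title: Transport Dating, Habitability Mapping and Organic-Matter
    Characterization of Deep-Sea Brine Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for athalassohaline deep-sea brine lakes and
    their seawater-brine interfaces. Dates sediment-brine contact by fitting
    a one-dimensional advection-diffusion transport model (closed-form
    complementary-error-function solution) to pore-water tracer profiles,
    with bootstrap uncertainty; maps magnesium / water-activity structure
    across the halocline, bins samples into named interface layers and
    locates habitability boundaries via monotone activity curves; and
    assigns CHNOS elemental formulas to ultra-high-resolution negative-mode
    exact masses, with van Krevelen coordinates, compound-class ratios and
    between-sample comparisons. Includes seeded synthetic-data generators
    for every input so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
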