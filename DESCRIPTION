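Package: bcl2dose
Title: BCL-2 Network Stress-Dose Modelling and Drug-Combination Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action modelling of the BCL-2 protein
    interaction network controlling mitochondrial outer membrane
    permeabilization (MOMP). Converts absolute protein concentrations of
    BCL2, BCL(X)L, MCL1, BAX and BAK into a stress-dose score (eta), the
    minimal BH3-only protein production over a 12 h stress window required
    to trigger MOMP, and extends the network with selective BCL2-family
    antagonists parameterized by dissociation constants. Includes
    dose-matrix synergy analytics (Webb fractional-product combination
    index, Loewe additivity excess, isobolograms), quantitative-immunoblot
    calibration math, correlation and clustering utilities, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
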