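Package: monofilm
Title: Langmuir Monolayer Isotherm Analysis and Mixing Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing surface pressure-area (pi-A) isotherms of
    Langmuir monolayers: extraction of characteristic descriptors (lift-off
    area, extrapolated area A0, collapse events, compression modulus Cs-1 and
    monolayer phase state), mixing thermodynamics of binary and ternary films
    (ideal mean molecular area, excess area, excess free enthalpy of mixing by
    excess-area integration over surface pressure), collapse-pressure based
    miscibility assessment under the two-dimensional phase rule, and
    Israelachvili critical packing parameter geometry for film-forming
    amphiphiles. A synthetic isotherm generator with closed-form ground truth
    supports validation of every analysis stage, including model membrane
    composition presets for normal (cholesterol/DPPC) and tumor
    (cholesterol/POPC) cell membranes and their interactions with
    alkylphosphocholine antitumor lipids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
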