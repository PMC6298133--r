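Package: glarginepk
Title: Mechanistic Subcutaneous Depot Absorption and Plasma
    Pharmacokinetics of Insulin Glargine 100 and 300 U/mL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the subcutaneous fate and plasma pharmacokinetics of
    insulin glargine formulated at 100 U/mL (Gla-100) and 300 U/mL (Gla-300).
    The model couples first-order precipitation of the injected solution into
    an amorphous depot, surface-area-limited (Nernst-Brunner) redissolution of
    the precipitate, a hexamer-dimer-monomer dissociation chain with
    volume-dependent non-specific degradation in subcutaneous tissue,
    first-order absorption of monomers into plasma, and saturable plasma
    clearance. Includes a multi-dose regimen engine (steady state, flexible
    injection intervals, product switching), trailing 24-hour exposure
    metrics, a seeded multi-start least-squares calibration module, a
    synthetic clamp-profile generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
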