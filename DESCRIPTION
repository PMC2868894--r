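Package: devoecd
Title: Coupled-Oscillator Circular Dichroism of Dimeric Chromophores
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: All-order DeVoe coupled-oscillator calculation of circular
    dichroism (CD) and absorption for assemblies of point-dipole
    oscillators, with Kramers-Kronig construction of complex
    polarizabilities from absorption band shapes.  Includes first-order
    analytic exciton-couplet and non-degenerate cross-term expansions,
    two-state atropisomer thermodynamics and mutarotation kinetics,
    analysis of solvent-series CD spectra (extrema, isodichroic points,
    elongation profiles, two-basis linear-combination tests), seeded
    synthetic-data generators for every pipeline input, and a command-line
    interface reading/writing CSV, JCAMP-DX and JSON assembly files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
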