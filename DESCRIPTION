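Package: hairpinES
Title: Design and Exchange Analysis of Hairpin RNA Excited States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for designing small hairpin RNAs with predefined
    low-populated excited states reachable by base-pair register shifts,
    and for characterizing ground-state/excited-state exchange by NMR
    relaxation dispersion. Implements the Laguerre closed-form and full
    Bloch-McConnell models of two-site chemical exchange for R1rho and
    CEST observables, per-residue and global fitting with Monte Carlo
    error estimation, van't Hoff/Eyring transition-state thermodynamics
    at the harmonic-mean temperature, a multi-state rate-matrix simulator
    of sequential register-shift pathways, a combinatorial stem designer
    with strong/weak base-pair and free-energy filters, and seeded
    synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
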