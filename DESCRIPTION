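Package: scgm
Title: Single-Cell Growth Model for Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a biophysical single-cell growth model for
    budding yeast that couples osmotic volume, turgor pressure and internal
    osmolarity through Kedem-Katchalsky membrane water flux and an
    elasto-viscoplastic (Hookean plus Bingham) thin-shell cell wall.
    Includes the closed-form growth law and steady states, a coupled
    mother-bud (and mother-two-bud) model with inter-compartment water and
    osmolyte exchange, piecewise-constant osmotic-shock protocols with a
    phenomenological HOG-type active response, chi-squared trajectory
    fitting of mother-bud volume time series with multi-start bounded
    least squares, and a synthetic-cohort generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
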