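Package: bgsmap
Title: Background-Selection B-Maps Under Non-Equilibrium Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the reduction in neutral pairwise diversity caused by
    linked purifying selection (the B-value, pi/pi0) along a chromosome,
    from weak to strong selection and under piecewise-constant
    population-size histories. Weak and moderate selection are modeled by a
    truncated Hill-Robertson system of two-locus moments with selection;
    strong selection by a structured coalescent over deleterious allelic
    classes extended to non-equilibrium demography with phase-type theory.
    Includes a multi-locus B-map engine with lookup tables, DFE weighting
    and an iterative interference correction, a Gamma-DFE fitting stage,
    and forward Wright-Fisher simulation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
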