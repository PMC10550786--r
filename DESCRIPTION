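Package: psgame
Title: Producer-Scrounger Games with a Competitiveness-Detection Trade-Off
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic two-phenotype producer-scrounger game in which
    strong competitors are better at monopolizing contested food while weak
    competitors are better at detecting prey. Solves the short-term Nash
    equilibrium of foraging-tactic frequencies at fixed group composition by
    best-reply dynamics, iterates a long-term survival/replacement dynamic of
    phenotype frequencies to the evolutionarily stable state, and provides
    parameter-sweep drivers, an equal-competitor benchmark solver, CSV output
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
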