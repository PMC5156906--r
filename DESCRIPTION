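Package: slimfunnel
Title: Structure-Informed Short Linear Motif Discovery for Calcineurin Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Position-class (PROSITE-style) scanning of calcineurin docking
    motifs (the pi-phi-LxVP family and PxIxIT dialects) together with the
    filter funnel used to nominate candidate substrates: intrinsic-disorder
    filtering of motif windows, phosphosite presence, and PxIxIT co-occurrence
    in disordered regions. Includes post-funnel analytics (phosphosite
    distance and orientation summaries, position probability matrices with
    information content, subcellular localization breakdowns), a seeded
    synthetic-proteome generator with planted ground truth for recovery
    scoring, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
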