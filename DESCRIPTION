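Package: hybtools
Title: Toolkit for Hyb-Format Chimeric RNA (CLASH/qCLASH) Hybrid Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reading, writing, validation, annotation, filtration, and
    descriptive analysis of hyb-format chimeric (hybrid) RNA sequence
    records produced by CLASH-family ligation experiments. Includes
    paired Vienna dot-bracket fold-record handling with concurrent
    hyb+fold iteration and mismatch checking, segment-type and miRNA
    annotation via user-selectable methods, predicate-based record
    filtration, five streaming descriptive analyses with plotting
    (including per-nucleotide miRNA binding profiles), command-line
    tools, and a seeded synthetic-data generator with ground truth for
    testing complete workflows without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
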