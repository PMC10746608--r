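Package: coreTF
Title: Core Transcription Factor Discovery from Selection-Scan Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate "core" transcription factors (TFs)
    orchestrating a selection signature, such as the gene lists compiled for
    mammal domestication, by combining two evidence channels: TFs that are
    themselves members of the selected-gene list, and TFs whose
    experimentally demonstrated targets (ChIP-seq-derived, ChEA-style gene
    set libraries) are over-represented in that list under a one-sided
    Fisher exact (hypergeometric) test with Benjamini-Hochberg adjustment.
    Provides per-TF pathway profiling with cross-TF shared-pathway
    intersection, regulatory and protein-interaction network construction
    with hub ranking, strict readers and writers for GMT libraries, gene
    lists and interaction tables, and a fully seeded synthetic-data
    generator with planted signal for end-to-end recovery and null
    calibration testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
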