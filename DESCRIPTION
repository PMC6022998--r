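Package: ltrcraft
Title: Classification, Insertion-Time Dating and RT Phylogenies of LTR
    Retrotransposons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for full-length LTR retrotransposon
    libraries: annotates elements with the six canonical retroelement protein
    domains (GAG, AP, RT, RNaseH, INT, ENV) by six-frame translated search
    against a lineage-labelled reference library, classifies elements into
    Gypsy/Copia superfamilies and lineages or the non-autonomous TRIM, LARD
    and TR-GAG classes, rescues unclassified elements with the 80/80/80
    similarity rule, dates insertions from 5'/3'-LTR divergence under the
    Kimura 2-parameter model, and builds lineage-annotated neighbor-joining
    trees from extracted reverse-transcriptase domains. Includes a synthetic
    element generator with known category, lineage and insertion age so every
    stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
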