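Package: flavimine
Title: Mining Flavinylation-Based Extracytosolic Electron Transfer Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics and structural-bioinformatics toolkit for
    discovering candidate substrates of the bacterial FMN transferase ApbE.
    Mines annotated prokaryotic genomes for genes co-localized with apbE
    (gene-neighborhood windows), scans proteins for the degenerate
    [S/T]GA[S/T] flavinylation motif, assigns best-match domain families from
    hmmsearch tabular output or a built-in PSSM scanner, summarizes candidate
    distributions across GTDB taxonomy, computes per-column information
    content from multiple sequence alignments, and detects structure-level
    signatures in coordinate models: Kyte-Doolittle transmembrane segments,
    bis-histidine heme-site geometry, Kabsch superposition, and
    motif-to-flavin-pocket distances. Includes a seeded synthetic-data
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
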