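Package: poolscreen
Title: Simulation, Quantification and Hit Calling for Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR knockout (GeCKO-style) screens
    read out by amplicon sequencing. Implements shift-tolerant sgRNA
    quantification from FASTQ reads (guides may drift around their canonical
    position in the amplicon; matching allows up to one mismatch and no
    indels inside the guide), count normalisation, per-guide enrichment
    testing against selection-free references, alpha-RRA style gene-level
    rank aggregation with permutation p-values, and a multi-criterion
    candidate-gene filter across a screen's sample hierarchy (plasmid, cell
    library, clones, regenerated tissues). A fully specified synthetic-screen
    generator with known per-gene fitness and per-guide efficiency provides
    ground truth for calibration and recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    DESeq2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
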