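Package: retroclip
Title: Transposable-Element-Aware Analysis of CLIP-Seq Protein-RNA
    Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise RNA binding protein interactions with
    transposable-element (TE) derived RNA from CLIP-Seq alignments:
    family-by-orientation enrichment against a transcript-abundance null
    model, read-coverage profiling on TE consensus coordinates, extraction
    and clustering of TE-specific 9-nt binding motifs, transcriptome-wide
    motif scanning with exact position-weight-matrix p-values, isoform-aware
    Poisson scan-statistic peak calling, and attribution of knockdown
    differential-expression effects to binding-site classes. Includes an
    adapter-ignorant iterative prefix aligner and a synthetic-data generator
    (toy genomes with TE insertions, multi-isoform genes, planted motifs,
    PCR duplicates and multi-mapping reads) so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
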