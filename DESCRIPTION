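Package: nucmorph
Title: Comparative Analysis of Nucleomorph Genomes with Ultrasmall Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of highly reduced nucleomorph
    genomes such as those of chlorarachniophyte algae. Provides a spliced-ORF
    gene caller aware of ultrasmall (18-23 nt) GT-AG spliceosomal introns,
    detection of telomeric tandem repeats, shared subtelomeric repeat units and
    exactly identical duplicated regions, protein homology search with
    single-linkage family construction, collinear synteny-block detection,
    cross-genome intron position conservation, genome summary statistics, and a
    deterministic synthetic-genome generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
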