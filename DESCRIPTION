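Package: repeatscape
Title: Graph-Based Repeat Landscape Analysis from Low-Coverage Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free characterization of the repetitive fraction of plant
    genomes from low-coverage paired-end reads. Reads are clustered into repeat
    families on a k-mer seeded similarity graph, clusters are annotated against a
    user-supplied repeat library and summarized as genome-proportion tables,
    tandem satellite monomers and their internally deleted length variants are
    detected and quantified, multi-species combined datasets yield shared versus
    species-specific family classifications, CenH3 ChIP-seq reads are mapped onto
    clusters under an edit-distance contract to measure centromeric enrichment,
    and reverse-transcriptase domains drive bootstrapped neighbor-joining trees of
    LTR retrotransposon families. A synthetic-data generator with full ground
    truth supports end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
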