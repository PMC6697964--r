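Package: TranscriptMarkers
Title: Genic SSR and SNP Marker Development from Transcriptome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for developing molecular markers from de novo transcriptome
    assemblies of non-model plants: mining perfect simple sequence repeats
    (SSRs) with unit-length-specific minimum repeat counts and canonical
    motif classification, locating the longest ATG-initiated open reading
    frame to partition transcripts into 5'UTR/CDS/3'UTR, characterizing
    single-nucleotide variants (depth/mapping-quality filtering,
    transition/transversion spectrum, high-resolution-melting SNP classes),
    germplasm diversity statistics (polymorphic information content, Jaccard
    similarity, UPGMA dendrograms), FPKM-based fold-change classification of
    differentially expressed genes, and genotype calling from
    high-resolution-melting fluorescence curves. A synthetic-data module
    generates every input with a known planted truth so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
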