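Package: cressomics
Title: Small RNA, Methylation, Expression and Assembly QC Analytics for
    the Pennycress Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream computational procedures for a chromosome-level
    plant genome resource: de-novo small-RNA cluster discovery and
    multi-library, multi-tissue consensus locus annotation with size-class,
    complexity, 5'-nucleotide and phasing metrics; rule-based curation of
    MIRNA hairpin candidates; genomic feature context summaries (density
    tracks, gene-density partitions, nearest-feature distances,
    TE-contained genes, ancestral karyotype block painting); whole-genome
    bisulphite sequencing summaries (coverage filtering, per-context
    levels, window tracks, stranded metaprofiles); a TMM-normalized Tau
    tissue-specificity expression atlas; k-mer genome-size estimation and
    depth-based duplicate-contig purging with BUSCO protection; and
    variant-class plus linkage-disequilibrium decay summaries. Seeded
    synthetic-data generators with recorded planted truth make every stage
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
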