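Package: putsnp
Title: Putative Unique Transcript Catalogues and Conservative SNP
    Consensus from Multi-Library 454 cDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Post-processing of de novo 454 cDNA assemblies from pooled,
    normalized libraries into a catalogue of putative unique transcripts
    (PUTs): read cleaning (N removal, polyA/T trimming), rescue of
    false-positive singletons by k-mer seeded alignment at a percent
    identity threshold, pileup SNP calling with a per-allele minimum read
    support rule, intersection of multiple callsets into a conservative
    consensus, classification of each SNP by the provenance (variety) of
    its supporting reads, synonymous/non-synonymous annotation from
    translated-alignment reading frames, treatment-origin partitioning of
    transcripts, keyword candidate screens, and polymorphism-level
    estimation over distinct catalogue nucleotides.  Includes a
    synthetic-data generator emulating a twelve-library, two-variety,
    three-treatment drought stress design so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
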