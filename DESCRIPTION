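Package: cimexvir
Title: Co-Occurrence Segment Screening and Phylogeographic Distance
    Analysis for Bed Bug Virome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analyses for RNA virome surveys of bed bugs
    (Cimex lectularius and Cimex hemipterus) and similar arthropod
    metatranscriptome studies. Identifies candidate genomic segments of
    multipartite viruses from sample-level transcript co-occurrence with
    RdRp-anchored conserved sequences (the V_co/T_co screen), extracts
    open reading frames in six frames with getorf-style stop-to-stop and
    start-to-stop semantics, computes uncorrected pairwise p-distances
    with within- and between-clade mean summaries for phylogeographic
    comparisons, and fits the simple linear regression relating per-sample
    Wolbachia and virus read percentages. A synthetic-data generator
    produces presence/absence matrices, divergent sequence families,
    abundance tables and ORF-bearing transcripts with known truth so the
    whole pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ape,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
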