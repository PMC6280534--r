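Package: rddmr
Title: Two-Condition Differential DNA Methylation Analysis with Small RNA
    and Expression Integration
Version: 0.1.0
Authors@R:
    person("J.", "Doe", email = "jdoe@example.com", role = c("aut", "cre"))
Description: Calls differentially methylated cytosines and regions (DMCs and
    DMRs) between two conditions from per-cytosine bisulfite methylation
    calls, using depth filtering, sliding-window Fisher exact tests with
    Benjamini-Hochberg control, candidate merging across CG/CHG/CHH contexts,
    shrinking to bounding DMCs, and a replicate-consistency robust index.
    Downstream modules place DMRs in genomic context (gene association,
    element classification, enrichment versus length-matched random regions,
    metagene profiles), connect 24-nt siRNA cluster abundance to DMRs, and
    integrate differential expression and GO enrichment for hypomethylated
    genes. A fully parameterised synthetic-study generator with planted
    signal makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
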