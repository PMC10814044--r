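Package: ugtsplice
Title: Junction-Probe Quantification and Cryptic 3' Splice-Junction
    Discovery for UGT1A Transcript Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying wildtype (v1) and variant (v2, v3) UGT1A
    transcripts in RNA-seq reads by exact matching of 30-nt junction-spanning
    probes, for anchored discovery of novel 3' splice junctions that use
    cryptic splice sites around exons 5a, 5b and 5bv, and for cohort-level
    deregulation statistics on paired tumour-normal designs (signed-rank
    tests, Spearman correlations, fold-variability summaries). Includes a
    splice-graph model of the UGT1A locus that encodes the known v1/v2/v3
    transcripts and ten novel 3'-variant transcript classes, a protein
    predictor for the truncated dominant-negative i2 isoforms, and a seeded
    read simulator that produces FASTQ cohorts with a ground-truth manifest
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
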