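Package: lncoexp
Title: Co-Expression Network Analysis of lncRNAs and mRNAs in Two-Genotype
    Stress-Response RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis pipeline for paired drought-stress /
    re-watering RNA-seq experiments contrasting a stress-tolerant and a
    stress-sensitive genotype. Computes FPKM from fragment counts, calls
    differential expression with a negative-binomial Wald test, builds
    Pearson-thresholded bipartite lncRNA-mRNA co-expression networks and
    summarizes their topology, finds cis co-located lncRNA/gene pairs from
    GFF3 annotation, performs GO/KEGG over-representation tests with
    optional gene-length bias correction via the Wallenius noncentral
    hypergeometric distribution, classifies transcription-factor responses
    across genotypes, and quantifies RNA-seq/qPCR concordance. Includes a
    negative-binomial study simulator with planted effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    xml2,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
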