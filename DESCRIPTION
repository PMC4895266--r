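Package: nmfiso
Title: Isoform Candidate Preselection by Penalized Non-Negative Matrix
    Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Shrinks the search space of candidate mRNA isoforms for a gene
    from multi-sample RNA-seq read counts. Reads are summarised into subexon
    bins, the bin-by-sample count matrix is normalised for sequencing depth
    and bin length, and a penalized non-negative matrix factorization under
    generalized Kullback-Leibler divergence is fitted repeatedly with random
    restarts. Binarized factor columns are expanded into biologically valid
    isoform candidates, filtered by splice-junction read support and by the
    frequency with which they recur across factorization runs. Includes a
    gap-statistic rank selector, GTF import/export of gene models and
    candidates, a synthetic multi-sample read-count simulator, and
    nucleotide-, exon- and transcript-level precision/recall evaluation of
    identified against annotated isoforms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
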