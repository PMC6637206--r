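Package: pleiocfdr
Title: Pleiotropy-Informed Conditional FDR Analysis of Paired GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the genetic-pleiotropy-informed conditional false
    discovery rate (cFDR) workflow for two sets of GWAS summary statistics:
    reading, validating and merging per-SNP association results, genomic-control
    diagnostics, stratified Q-Q / fold-enrichment / conditional TDR curves,
    empirical per-SNP cFDR in both conditioning directions and the conjunctional
    cFDR (ccFDR), greedy clumping of significant SNPs into independent loci, and
    LD-proxy replication cross-checking. A four-component mixture simulator of
    paired z-scores with known ground truth makes the whole pipeline testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
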