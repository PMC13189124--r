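Package: pqtlmr
Title: Cis-Mendelian Randomization of Plasma Protein QTLs with
    Colocalization and Knowledge-Graph Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cis-Mendelian randomization linking plasma protein
    quantitative trait loci (pQTLs) to disease and biomarker GWAS. Implements
    instrument selection (cis window, minor allele frequency and F-statistic
    filters, palindrome exclusion, LD clumping against a reference panel),
    generalized-least-squares IVW and MR-Egger estimation with correlated
    instruments, Rucker model selection, leverage/outlier and Steiger
    filtering, approximate-Bayes-factor colocalization, replication and
    positive-control assessment, directional concordance profiling, and
    knowledge-graph community detection with pathway enrichment. A seeded
    simulator generates reference panels, summary statistics with known
    ground truth, and annotation fixtures so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
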