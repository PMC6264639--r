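Package: chromMI
Title: Detection of Classification-Informative Chromatin-State Windows by
    Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans genome-wide chromatin-state segmentations (ChromHMM
    mnemonic BED tracks) from a set of epigenomes for genomic windows whose
    per-sample state profile is informative about a user-supplied
    classification of those samples. Each window's profile is collapsed per
    sample with a majority rule, scored against the classification with a
    mutual-information statistic, assigned an empirical p-value from a
    composition-preserving permutation null, and adjusted genome-wide with
    the Benjamini-Hochberg false discovery rate. Downstream helpers
    summarize per-group epigenetic change patterns, retrieve overlapping
    genes, test Gene Ontology term enrichment with one-sided Fisher tests,
    and evaluate robustness to epigenome downsampling. A synthetic-data
    generator plants group-correlated windows on toy genomes with known
    truth for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
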