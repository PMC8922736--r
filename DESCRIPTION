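Package: degbench
Title: Benchmarking Differential Expression Methods on Large-Sample RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking toolkit for differential expression (DE) analysis of
    two-condition RNA-seq count data with large per-condition sample sizes. It
    provides a Wilcoxon rank-sum DE pipeline (low-expression filtering, TMM
    scaling factors, counts-per-million, rank-sum testing, Benjamini-Hochberg
    correction), a deliberately simple negative-binomial Wald comparator that
    exhibits the parametric failure mode under outlier contamination,
    permutation-null and semi-synthetic ground-truth dataset construction,
    false-discovery-proportion and power evaluation across threshold and
    sample-size sweeps, negative-binomial goodness-of-fit diagnostics, and a
    seeded negative-binomial count simulator with library-size variation and
    outlier contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
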