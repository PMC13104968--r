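Package: paleoimmune
Title: Selection Scans, Genetic Correlation, Colocalization and Signed
    Pathway Activity for Ancient-DNA Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking time-series signals of natural selection in
    dated ancient genomes to present-day disease biology. Provides a
    Wright-Fisher forward simulator of dated cohorts with admixture
    structure, a per-variant weighted time-trend selection scan producing
    GWAS-compatible summary statistics, a permutation-calibrated polygenic
    score trajectory test, LD-score regressions for heritability-scale
    parameters, cross-track genetic correlation with block-jackknife
    standard errors and covariance-aware meta-analysis, enumeration-based
    colocalization and single-causal fine-mapping with credible sets,
    hypergeometric pathway enrichment with permutation tests of
    immune-label excess, and a signed pathway-activity statistic that
    infers whether selection increased or decreased the activity of
    biological processes from protein quantitative trait loci.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
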