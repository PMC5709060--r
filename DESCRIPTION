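Package: methdriver
Title: Driver-Mutation and DNA-Methylation Association Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pan-cancer style analysis toolkit linking somatic driver-gene
    mutations to DNA-methylation alterations measured on Illumina 450K-type
    beta-value matrices. Provides probe filtering and hyper/hypomethylation
    calling against matched normals, methylome principal-component and
    CpG-subset association scans, per-sample genome-wide methylation-alteration
    indices (HyperZ/HypoZ), an exhaustive driver-gene by probe rank-sum
    association scan with Benjamini-Hochberg correction and permutation-based
    empirical false-discovery-rate estimation, mutation-anchored methylation
    subtyping, and a direction-consistent mutation-to-methylation-to-expression
    integration procedure with hypergeometric gene-set enrichment. Includes a
    synthetic-cohort generator with planted ground-truth effects for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    matrixStats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
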