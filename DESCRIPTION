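Package: plasmaSCNA
Title: Copy Number, Fragment Size and Concentration Dynamics of Circulating Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating cell-free DNA (cfDNA) from
    shallow whole-genome sequencing: bin-level read counting, GC-bias
    correction, median-normalized log2 copy-number profiles, run-length
    calling of somatic copy number alterations (SCNAs), in-silico fragment
    size selection (90-150 bp) to enrich tumor-derived fragments, and the
    trimmed median absolute deviation from copy-number neutrality (tMAD)
    statistic for circulating tumor DNA detection.  Also provides the
    longitudinal concentration statistics used when monitoring cfDNA during
    chemo-radiotherapy (Bland-Altman limits of agreement, baseline
    summaries, change from baseline by histology, an exact Wilcoxon rank-sum
    test with midranks, Spearman correlation) and a fully seeded synthetic
    data generator so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
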