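Package: tcscensus
Title: Census of Two-Component Signal Transduction Systems in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial genes as histidine kinases, response
    regulators, or hybrid kinases from Pfam domain annotations; detects
    orphan two-component-system genes by start-point distance on the
    linearized genome; computes genome-normalized repertoire statistics
    (histidine kinases per 100 protein-coding genes, RR/HPK ratio, percent
    hybrid) and cohort comparisons with t-tests, ANOVA and bootstrap
    confidence intervals; clusters genomes by signaling repertoire with
    k-means and silhouette-based model selection; and fits power laws
    relating protein abundance to nutrient concentration. Includes a
    synthetic-genome generator with planted ground truth so every pipeline
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
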