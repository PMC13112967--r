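Package: dhetgscreen
Title: Combinatorial Differential-Expression Screening of Druggable Target
    Genes in Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Leonie", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially higher expressed target genes (DHETGs)
    per neuronal cell type from a cells-by-genes CPM expression matrix with
    region/subclass/class annotations and a druggable-genome target catalogue.
    Implements Wilcoxon rank-sum marker testing on log2(1+CPM) with Bonferroni
    or Benjamini-Hochberg correction, configurable selection criteria (fold
    change, expressing-cell fraction beta, contrast-expression cap),
    intra-regional one-vs-one and one-vs-all contrast plans, inter-regional
    contrasts against pooled region groups, set combination by intersection,
    Venn decomposition and majority rule, per-target-class reporting, and a
    synthetic zero-inflated log-normal data generator with planted marker
    genes for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
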