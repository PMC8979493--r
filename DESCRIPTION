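Package: depmex
Title: Differential Dependencies and Mutually Exclusive Feature Sets from
    Perturbation Screens
Version: 0.1.0
Authors@R:
    person("DepMex", "Maintainers", email = "maintainers@depmex.example.org",
           role = c("aut", "cre"))
Description: Identifies differential genetic dependencies in quantitative
    perturbation-screen score matrices (e.g. CRISPR-Cas9 gene-effect scores)
    with one- versus two-component t-mixture model selection, scores each
    sample by the log posterior odds of membership in the responsive mixture
    component, and searches a binary matrix of annotated mutation and
    cell-type features for approximately mutually exclusive feature sets
    associated with each differential dependency. The search is an exact
    combinatorial optimization of an exclusivity-penalized, phenotype-weighted
    coverage objective, followed by conditional-permutation model selection,
    fixed-margin (curveball) permutation significance testing, and
    Benjamini-Hochberg false discovery rate control. Includes a seeded
    synthetic-cohort generator with planted ground truth, file readers and
    writers for screen matrices and mutation tables, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
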