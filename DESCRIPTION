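Package: faststree
Title: Fast Species-Tree Estimation from Gene Trees with Coalescent Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating species trees from collections of gene trees
    and for evaluating such estimators by simulation. Implements the fast
    combination methods used in multi-locus phylogenomics: majority and greedy
    (extended majority) consensus, the GLASS minimum-distance method,
    minimize-deep-coalescence (MDC) scoring including the constrained variant
    for unrooted and partially resolved gene trees, and duplication and
    duplication-loss reconciliation scoring, together with a hill-climbing
    species-tree search over these criteria. A synthetic-data module simulates
    gene trees under the multispecies coalescent within a species tree,
    branch-length-perturbed gene trees without incomplete lineage sorting, and
    sequence evolution under GTR+Gamma with insertions and deletions while
    tracking true alignment homology. Gene trees are estimated at desk scale
    with logdet distances, neighbor joining and nonparametric bootstrap
    support, and accuracy is scored with the missing-branch (false negative)
    rate backed by Wilcoxon signed-rank comparisons with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
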