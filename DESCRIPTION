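Package: haplogeo
Title: Chloroplast Haplotype Phylogeography, Demographic Inference and
    ABC Model Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for haplotype-based phylogeography of organellar
    (haploid, non-recombining) sequence data: indel recoding to binary
    characters, haplotype collapsing and statistical-parsimony networks,
    Pons & Petit ordered and unordered diversity statistics (H_S, H_T,
    G_ST, N_ST) with a permutation contrast test, distance-based AMOVA
    with Phi statistics, Mantel tests of isolation by distance, mismatch
    distribution analysis under demographic and spatial expansion models
    with parametric bootstrap, Tajima's D and Fu's F_S neutrality tests,
    a haploid coalescent simulator for divergence-with-bottleneck and
    progenitor-derivation speciation models, and approximate Bayesian
    computation with Box-Cox/PLS summary reduction, rejection, GLM
    regression adjustment, marginal densities and Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    mixOmics,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
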