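Package: bootmods
Title: Bootstrap-Stable Coexpression Modules for Two-Population RNA-seq Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing host transcriptomic responses
    across two populations in a factorial (population x infestation-stage) RNA-seq
    design: count filtering and TMM normalization, log-CPM transformation,
    per-gene negative-binomial GLM differential expression with interaction
    contrasts and Benjamini-Hochberg adjustment, signed-hybrid weighted
    coexpression network construction with topological overlap, a bootstrap
    module-stability consensus filter (resampled networks, overlap matching,
    per-gene reliability), module-eigengene factorial ANOVA and response-pattern
    classification, Bray-Curtis nMDS ordination with PERMANOVA, and Fisher
    exact gene-set enrichment. Includes a negative-binomial simulator that
    plants coexpression modules with population-by-infestation response
    categories and full ground truth, so every stage has a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
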