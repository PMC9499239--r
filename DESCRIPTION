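Package: InterCellBN
Title: Cell Type Interaction Networks from Case-Control scRNA-Seq
    Compositions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers differential cell-type to cell-type interaction networks
    from case-control single-cell RNA-seq data. Per-sample cell type fractions
    are binarized with a two-component Gaussian mixture, a discrete Bayesian
    network over cell types is learned by a restrict-maximize scheme
    (Hiton-PC candidate screening followed by BIC-penalized hill climbing),
    and edge confidence is scored by repeated structure learning on cell
    subsamples. Differential edges between conditions are then explained at
    the gene level by a ligand-target regression: a LASSO model with one
    shared activity coefficient per ligand, built from a ligand-target
    regulatory-potential matrix and evaluated by target-wise cross-validation,
    with autocrine and shuffled-matrix controls. A synthetic-data simulator
    generates case-control datasets from a known ground-truth network so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    yaml,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
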