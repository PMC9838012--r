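Package: drivergcn
Title: Cancer Driver Gene Prioritization from Multiple Heterogeneous Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cancer driver genes by integrating a gene-gene
    (protein-protein interaction) network, a gene-outlying-gene network and a
    gene-miRNA network. Gene representations are learned with parameter-sharing
    heterogeneous graph convolution layers, a bilinear neighbour-interaction
    layer, a shared self-attention layer and convolutional feature fusion, and
    genes are scored through a multi-task objective (node classification plus
    link reconstruction) combined by a logistic regression model. Includes
    feature construction from multi-omics summary tables (mutation,
    methylation and expression rates, outlying-expression z-scores, Gaussian
    Interaction Profile kernel similarities, random-walk node embeddings), a
    synthetic data generator with planted driver signal, stratified
    cross-validation and ablation tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    glmnet,
    methods,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
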