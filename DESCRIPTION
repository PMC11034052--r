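Package: cloneGAN
Title: Adversarial Autoencoder Clustering of Single-Cell Copy-Number
    Profiles Informed by Unpaired scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers clonal copy-number substructure (intra-tumor
    heterogeneity) from single-cell DNA sequencing data. An autoencoder
    learns a low-dimensional representation of per-cell copy-number
    profiles while a generative adversarial network pushes expression
    vectors generated from that representation towards the distribution
    of unpaired single-cell RNA-seq data from the same cell line, so the
    embedding fuses complementary information from both omics. Cells are
    clustered in the latent space with full-covariance Gaussian mixture
    models selected by BIC under small-cluster validity and patience
    stopping rules. Includes preprocessing for copy-number and UMI count
    matrices, external (ARI, NMI) and internal (silhouette,
    Calinski-Harabasz) clustering indices, and a coupled scDNA/scRNA
    simulator with planted clonal structure for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
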