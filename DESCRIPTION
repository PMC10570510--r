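Package: HabitatCT
Title: Habitat Imaging of Inflamed Lung CT for Pneumonia Versus Pneumonitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partitions inflamed lung CT into phenotypically coherent
    subregions ("habitats") by SLIC oversegmentation of a four-channel
    composite image (lung/mediastinal window intensities plus their local
    entropy maps), population-level hierarchical clustering of superpixel
    statistics with gap-criterion selection of the habitat count, and
    quantification with an 88-feature multiregional spatial interaction
    (MSI) bank including left/right symmetric-difference features. Ships a
    synthetic lung phantom generator with paired clinical-blood tables,
    boosted classification-tree modelling with SMOTE nested inside
    leave-one-out cross-validation, a clinical-blood benchmark and
    composite/cascading models, and Bayesian pre-/post-test probability
    reporting for the pneumonia versus immune checkpoint inhibitor
    pneumonitis diagnostic problem.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    rpart,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
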