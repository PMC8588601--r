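Package: SynScreen
Title: Coiler Phenotyping, Literature Ranking and RT-QuIC Analytics for
    alpha-Synuclein Drug-Repurposing Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for a multi-stage drug-repurposing screen built
    around a C. elegans model of alpha-synuclein-mediated dopaminergic
    dysfunction. Quantifies the coiler motor phenotype from multi-worm
    video via shape circularity (4*pi*A/P^2) with a 0.6 coiling cut-off,
    links detections into tracks and computes population coiler scores and
    duration-weighted speeds; ranks candidate compounds against a known
    set by TF-IDF entity centroids, cosine similarity and random-walk-
    with-restart graph diffusion with leave-one-out validation (ROC/AUC,
    precision-recall, rank-sum); and calls RT-QuIC seeding positivity from
    kinetic ThT fluorescence plates using a mean-background-plus-5-SD
    threshold with a one-of-four replicate rule and Fisher exact group
    comparison. Includes seeded synthetic-data generators (worm recordings
    with ground truth, topic-structured corpora, RT-QuIC plates) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Classification, GraphAndNetwork
RoxygenNote: 7.3.3
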