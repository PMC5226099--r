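Package: enhancerStack
Title: Stacked Random-Forest/SVM Prediction of Enhancers from Histone-Mark Peaks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts enhancer elements in 200-bp genomic windows by stacking
    per-tissue random-forest base classifiers under a radial-basis-function
    support-vector meta-classifier. Features are min-max normalized histone
    modification peak signals (ENCODE broadPeak) or DNA k-mer frequencies;
    labels come from EP300 peaks or CAGE-defined enhancer catalogues. Includes
    k-means-guided 1:10 negative sub-sampling for the genome-scale class
    imbalance, tree-vote confidence scores weighted by held-out F-scores as
    meta-features, (C, gamma) grid search under stratified 10-fold
    cross-validation on the balanced error rate, a full evaluation suite
    (precision, recall, sensitivity, specificity, F-score, accuracy, ROC and
    AUC), and a synthetic multi-tissue epigenome generator for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
biocViews: Epigenetics, FunctionalPrediction, Classification, ChIPSeq
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
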