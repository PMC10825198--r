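Package: ezloc
Title: NLP Classification of Seizure Semiology Descriptions for Epileptogenic-Zone Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical natural-language-processing pipeline that classifies
    free-text seizure semiology descriptions into epileptogenic-zone
    categories (left vs right hemisphere; temporal vs extra-temporal;
    frontal vs posterior). Provides text normalization for Italian
    clinical prose (abbreviation expansion, lemmatization, stop-word
    removal), two document representations (a mixed character/word n-gram
    bag-of-words and word-embedding pooling by unweighted or TF-IDF-weighted
    averaging), a seed-deterministic skip-gram negative-sampling embedding
    trainer, intrinsic embedding evaluators (word similarity, analogy,
    outlier detection), repeated stratified nested cross-validation over
    sparse L1 logistic regression and SVM classifiers with
    support-weighted binary metrics, and a synthetic corpus generator with
    plantable class signal so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    e1071,
    jsonlite,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
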