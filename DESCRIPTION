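Package: pmrtopics
Title: Topic Modeling of Patient Medication Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines patient-written drug reviews for latent topics and relates
    them to satisfaction ratings. Provides eligibility filtering of review
    records (spam, empty-comment and under-age rules), text preprocessing to a
    document-term matrix (tokenization, bigram merging, stopword removal,
    Porter stemming with stem completion), latent Dirichlet allocation fitted
    by collapsed Gibbs sampling with density-based selection of the number of
    topics, per-review primary-topic assignment, and stratified topic-share
    and rating analyses (Fisher exact, Welch t, one-way ANOVA). A synthetic
    review generator with known ground truth makes the whole pipeline testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
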