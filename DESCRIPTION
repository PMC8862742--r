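Package: polarlex
Title: Partisan Polarization Analysis of Lexicon-Filtered Short-Text Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying partisan differences in short political
    texts such as legislator tweets. Provides lexicon-based corpus
    filtering (vaccine, COVID-19 and other infectious-disease term sets),
    descriptive party-by-characteristic contingency tests, differential
    unigram/bigram frequency testing with Bonferroni control, latent
    Dirichlet allocation fitted by collapsed Gibbs sampling with UMass
    coherence-based selection of the topic count, per-party mean topic
    representation, a monthly polarization index (sum of absolute
    differences in topic representation between parties), and epidemic
    wave segmentation from daily case counts. Includes a synthetic corpus
    generator that plants known topic structure and polarization trends
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
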