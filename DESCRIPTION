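Package: bayescner
Title: Chemical Named Entity Recognition with an Arcsine-Transformed
    Naive Bayes Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognizes and extracts chemical named entities (CNEs) from
    scientific text using a naive Bayes classifier over character
    multi-n-gram descriptors of tokens and their context windows.
    Conditional class probabilities are aggregated through the bounded
    arcsine transform into B-statistics, calibrated into probabilities of
    belonging (Pc) and not belonging (Pnc) to a chemical entity, and
    thresholded to extract whole entities from running text.  Includes
    readers and writers for CHEMDNER-style corpus files, leave-one-out and
    k-fold cross-validation with invariant-accuracy (AUC) scoring, a
    seeded synthetic corpus generator with gold entity spans, per-character
    colour rendering of predictions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
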