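Package: rbpregulon
Title: Coordination of RNA-Binding Proteins with Their mRNA Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how RNA-binding proteins (RBPs) coordinate the
    expression of their target mRNAs in budding yeast. Provides the
    co-expression statistics relating an RBP's expression to the mean,
    standard deviation and coefficient of deviation (CD) of its targets'
    log expression across conditions; a wild-type versus deletion-strain
    degradation-efficiency analysis with a variance-ratio test on target
    CD; a transcription-factor/RBP Hill-kinetics gene-regulation model
    with a Monte-Carlo phase diagram classifying regulator-target
    relationships over the (m, j) parameter plane; and seeded synthetic
    data generators that plant known co-regulation and variance-damping
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
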