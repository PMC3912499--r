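Package: gennet
Title: Grammatical Evolution Neural Networks for Multi-Omics Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves artificial neural network classifiers by grammatical
    evolution: variable-length codon genomes are decoded through a BNF grammar
    into weighted activation-node trees (PADD/PSUB/PMULT/PDIV) that select
    input variables, weights and topology simultaneously. An island-model
    genetic algorithm with migration searches for networks maximising balanced
    classification accuracy under stratified k-fold cross-validation. Includes
    a frequency-based variable filtering stage, a meta-dimensional integration
    stage that combines best models across omics layers (copy number,
    methylation, miRNA, expression) to predict a binary clinical outcome, an
    exact Wilcoxon signed-rank test for model comparison, and a synthetic
    multi-layer data generator with planted main effects and planted
    non-linear (XOR-type) within- and cross-layer interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
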