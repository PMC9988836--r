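Package: strainscan
Title: Modifier-Locus Discovery in Inbred Mouse Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A statistical-genetics toolkit for discovering and prioritizing
    modifier loci of binary traits in inbred mouse strain panels. Provides
    exact contingency tests for strain susceptibility screens, chi-square
    linkage scans in backcross cohorts, efficient mixed-model association
    (EMMA-style maximum-likelihood variance-component fitting with
    likelihood-ratio SNP tests), Viterbi hidden-Markov-model genotype
    imputation against phylogenetically similar reference strains,
    SVM-ensemble functional prioritization over weighted gene networks, and
    a combined gene score merging genetic and functional evidence. Includes
    synthetic-data generators (structured strain panels, two-locus
    complementation trait models, backcross meiosis under the Haldane map
    function, planted-module networks) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
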