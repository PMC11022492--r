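Package: apisim
Title: Simulation and Genetic Evaluation of Honeybee Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of closed honeybee breeding programs with
    controlled (single-sire or pseudo-sire) insemination of breeding queens
    and open mating of drone-producing queens, together with the
    haplodiploid-specific additive relationship matrix over queens, sire
    (pseudo-sire) entries and worker groups, its sparse inverse, and AI-REML
    estimation of correlated queen and worker genetic effects from colony
    phenotypes. Supports deliberate mis-specification of the sire model in
    the estimation pedigree, gene-dropping verification of the relationship
    recursion, BLUP-based genetic trends, and replicate batteries that
    quantify bias and standard error of variance-component estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
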