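Package: hybridscan
Title: Coalescent Tests of Homoploid Hybrid Speciation from SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and test homoploid hybrid speciation from
    biallelic SNP panels: f3/f4/D (ABBA-BABA), f4-ratio and f-branch
    statistics with block-jackknife standard errors; topology weighting of
    per-window gene trees; approximate Bayesian computation model choice
    between an instantaneous hybrid-origin scenario and introgression
    alternatives; and ploidy/aneuploidy diagnostics from allele balance and
    scaffold coverage. A compiled structured-coalescent simulator with
    population splits and admixture pulses generates SNP panels, gene trees
    and read counts under explicit demographic scenarios, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    nnet,
    MASS,
    vcfR,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
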