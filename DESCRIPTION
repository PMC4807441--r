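Package: hybridzone
Title: Geographic Cline Fitting and Multilocus Hybrid Zone Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing hybrid zones from codominant multilocus
    genotypes and a haploid mitochondrial marker. Fits sigmoid geographic
    clines to allele-frequency-by-distance data by maximum likelihood with
    AIC model selection and 2-unit support limits, tests cline concordance
    and coincidence with a constrained-versus-free likelihood ratio test,
    and predicts neutral cline widths from time since secondary contact and
    dispersal. Includes within-population disequilibrium statistics (exact
    Hardy-Weinberg tests, F_IS, Weir-Cockerham F_ST, composite linkage
    disequilibrium, cytonuclear disequilibrium, false discovery rate
    control), an EM admixture estimator with the Evanno delta-K heuristic,
    maximum-likelihood hybrid indices from parental allele-frequency
    differentials, Hartigan's dip test of unimodality with Monte Carlo
    p-values, and a seeded hybrid-zone genotype simulator with known truth
    for validating every stage. Reads and writes Genepop and CSV genotype
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
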