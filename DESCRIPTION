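Package: sweepintro
Title: Selective-Sweep Scanning and Archaic-Introgression Mapping with
    Coalescent Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome scans for recent positive selection and archaic
    (Denisovan/Neanderthal-like) introgression in a target population
    contrasted with a comparison population. Implements the component
    statistics of the Composite of Multiple Signals (CMS) score (iHS,
    XP-EHH, delta-iHH, FST, delta-DAF) and their naive-Bayes combination
    trained on coalescent simulations; ABBA-BABA D with 1-Mb block
    bootstrap, the window-level U statistic and its variance-normalised
    D*, an S*-style dynamic-programming haplotype scan, and an f4-ratio
    admixture-fraction estimator with ghost-source correction; sweep and
    introgression dating; and Gene Ontology over-representation by
    genomic-window resampling. Ships a coalescent simulator (ancestral
    recombination graph with piecewise demography, migration, admixture
    pulses and structured selective-sweep phases) encoding a fitted
    two-population Han-Tibetan demographic model, used both to generate
    synthetic study panels and to calibrate empirical p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
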