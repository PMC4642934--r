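Package: hetrelax
Title: Mutation Rate Estimation from the Relaxation of Local
    Heterozygosity Against the Recombination Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the per-generation point mutation rate of diploid
    genomes by calibrating the relaxation of local heterozygosity with
    genetic distance against coalescent simulations run under the same
    demography and a perturbed recombination map.  Implements the H_S(d)
    relaxation statistic, a gamma model of genetic-map error with a
    pseudo-count prior, a full (non-Markovian) ancestral-recombination-graph
    simulator for diploid samples, variance-weighted spline interpolation of
    calibration curves, leave-one-chromosome jackknife standard errors, and
    post-fit corrections for genotype error, non-crossover gene conversion,
    and base-content mutability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
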