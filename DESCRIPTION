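Package: rhomap
Title: Recombination Landscapes from a Single Pair of Genomes via a
    Markov-Modulated Sequentially Markovian Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint inference of demographic history and the spatial variation
    of the population recombination rate (rho = 4*Ne*r) along a genome from a
    single pair of haploid sequences (or one unphased diploid).  The genealogy
    process of the pairwise sequentially Markovian coalescent (SMC') is
    modulated by a hidden Markov chain of discretised Gamma recombination-rate
    categories, yielding a hidden Markov model over {TMRCA interval, rate
    category} pairs.  Provides maximum-likelihood fitting (Powell's method)
    with cubic-spline demographies, AIC model selection against a homogeneous
    null, posterior decoding into single-nucleotide and binned recombination
    maps, time-restricted decoding, map comparison (Pearson/Spearman, UPGMA
    clustering with bootstrap support), and coalescent simulators for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
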