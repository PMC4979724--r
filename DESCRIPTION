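Package: clinezone
Title: Spatiotemporal Analysis of Hybrid-Zone Clines from Microsatellite
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising a moving or widening hybrid zone from
    diploid microsatellite genotypes sampled in two eras. Reads GenePop and
    CSV genotype tables, pools collection sites by geographic proximity with a
    pairwise-FST guard, computes per-population diversity statistics
    (observed/expected heterozygosity, G_IS, effective and rarefied allele
    numbers, private alleles, Hardy-Weinberg and linkage-disequilibrium
    permutation tests, Weir-Cockerham theta), estimates maximum-likelihood
    hybrid indices with profile-likelihood intervals, projects populations
    onto a one-dimensional transect, fits Szymura-Barton geographic clines
    with optional exponential tails by MCMC with AIC model selection, and
    provides reciprocal constraint tests and stratified subsampling for
    comparing cline centre and width between sampling eras. A synthetic
    hybrid-zone genotype generator with known truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
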