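Package: hicsubcomp
Title: Probabilistic Sub-Compartment Inference from Trans-Chromosomal Hi-C Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of nuclear sub-compartment
    probabilities for genomic bins from inter-chromosomal (trans) Hi-C
    contacts. Models observed trans contact counts as Poisson draws whose
    rates factorize over nonnegative per-bin compartment scores, with a
    two-parameter polynomial correction for the Rabl configuration
    (centromere/telomere clustering across chromosomes). Includes a
    coordinate-ascent optimizer with convex per-locus subproblems and
    Newton updates for the Rabl coefficients, a forward simulator with
    down-sampling and population-mixture construction, AIC-based selection
    of the number of sub-compartments, per-bin information content as a
    heterogeneity measure, and readers/writers for pairs, chrom.sizes,
    BED, bedGraph and tabular score formats.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
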