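Package: elrtcall
Title: Multi-Sample SNP Calling from Read Counts with an Estimated
    Likelihood-Ratio Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Frequentist SNP calling for diploid samples from per-locus read
    counts. Each candidate locus is tested for a non-zero variant-allele
    frequency with an estimated likelihood-ratio test under a Hardy-Weinberg
    binomial-error model, the nuisance error rate being profiled out in
    closed form. Because the null parameter sits on the boundary of the
    parameter space, p-values are calibrated against a zero-inflated scaled
    chi-square null whose two parameters are estimated genomewide, and calls
    are made under Benjamini-Hochberg false discovery rate control. Includes
    a generative read-count simulator (generalized-Poisson coverage,
    truncated-normal error rates, uniform allele-frequency strata),
    evaluation metrics (FDR, power, F1, Fmax, Ti/Tv), readers and writers for
    count tables, samtools mpileup text, exclusion lists and VCF, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
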