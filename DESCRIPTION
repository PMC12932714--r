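Package: isoellipse
Title: Bayesian Standard Ellipse Analysis of Isotopic Niche Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying the isotopic niche of consumers from
    carbon and nitrogen stable isotope data. Implements baseline
    standardization of individual delta-13C and delta-15N values (range
    scaling of carbon, trophic-position anchoring of nitrogen via a
    trophic discrimination factor), maximum-likelihood and Bayesian
    standard ellipse areas (SEA, SEAc, SEAb) fitted per consumer group
    and year with a conjugate normal-inverse-Wishart Gibbs sampler,
    Gelman-Rubin convergence diagnostics, pairwise posterior-probability
    comparisons of niche areas between years, SEAc ratios against a
    reference year, highest-density intervals and kernel-density posterior
    modes, plus a synthetic-data generator that emulates group-by-year
    bivariate-normal isotope clusters for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
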