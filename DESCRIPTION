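Package: boldwvar
Title: Scale-Resolved Wavelet Variance Analysis of BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximal overlap discrete wavelet transform (MODWT) of
    regional fMRI BOLD time series with least-asymmetric Daubechies
    filters, exact scale-based variance and energy decomposition, and
    unbiased wavelet-variance estimation with chi-square confidence
    intervals based on conservative equivalent degrees of freedom.
    Includes the frequency-band mapping of decomposition levels, a
    seeded generator for synthetic signals and 2x2 group-by-condition
    cohorts with genotype and CpG-methylation covariates, and the
    downstream inferential workflow: factorial analysis of covariance
    with partial eta-squared effect sizes, split-plot repeated-measures
    ANOVA for cognitive load, post-hoc t-tests, Benjamini-Hochberg
    false-discovery-rate control, Fisher r-to-z comparison of
    correlations, blockwise stepwise multiple regression, and an exact
    Hardy-Weinberg equilibrium test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
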