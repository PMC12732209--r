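Package: igrp
Title: Representative Points and Quantile-Revised Inference for the
    Inverse Gaussian Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete approximation of the inverse Gaussian (Wald)
    distribution by Monte Carlo, quasi-Monte Carlo and mean-square-error
    (principal point) representative points, with applications to low-order
    moment estimation, probability-weighted kernel density estimation and
    resampling.  Also provides maximum likelihood fitting of the two- and
    three-parameter inverse Gaussian models by analytic formulas or
    sequential number-theoretic optimization (SNTO), Harrell-Davis and
    Sfakianakis-Verginis nonparametric quantile estimators for revising
    samples before fitting, and distributional accuracy measures
    (L2 distances on cdf and pdf, Kullback-Leibler divergence, absolute
    bias index) together with Kolmogorov-Smirnov goodness-of-fit
    indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
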