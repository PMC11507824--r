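Package: superexon
Title: Superstatistical Analysis of Exon-Length Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats the ordered exon lengths of a chromosome as a discrete
    time series and analyses it in the superstatistical framework: empirical
    densities on a linearly growing bin scale, autocorrelation and
    double-exponential timescale extraction, windowed local gamma and
    inverse-gamma fits, gamma/inverse-gamma mixing distributions of the local
    intensive parameter, closed-form q-Gamma and inverse q-Gamma marginals
    with Levenberg-Marquardt fitting, and Bayesian model comparison via
    nested-sampling evidences and Jeffreys' scale. Includes a synthetic
    series generator with ground truth so the whole pipeline is testable
    offline, and GFF3/TSV input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
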