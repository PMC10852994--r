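Package: conjCR
Title: Spatial Confidence Regions for Conjunctions of Excursion Sets
Version: 0.1.0
Authors@R:
    person("conjCR", "Developers", email = "conjcr@example.org",
           role = c("aut", "cre"))
Description: Confidence regions for the intersection (and, via De Morgan
    transforms, the union) of excursion sets of several spatially varying
    target functions estimated by pixelwise linear models. The regions are
    nested level sets of the standardised minimum field, calibrated by a
    wild t-bootstrap of a supremum statistic taken over the combinatorial
    segments of the estimated conjunction boundary. Includes a synthetic
    image simulation harness (smoothed circle, square and ramp signals with
    smoothed, optionally cross-correlated, Gaussian or heavy-tailed noise)
    for verifying empirical coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
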