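Package: elevrange
Title: Thermal Physiology, Habitat and Competition Limits on Elevational Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for testing three hypotheses about what sets
    the elevational range limits of tropical montane songbirds: thermal
    physiology (broken-stick metabolic models projected over an elevational
    temperature lapse and inverted at a 2 x BMR sustainability threshold),
    habitat structure (tree-type proportions by cumulative diameter, a
    touch-pole understorey index and a forest-floor principal-component
    index), and interspecific competition (distance to the nearest congener
    territory entered as a quadratic term). Abundance is modelled with
    zero-inflated Poisson N-mixture models fitted by maximum likelihood with
    detection covariates, two-step AICc model selection and
    parametric-bootstrap goodness of fit. A synthetic-data module emulates
    the full field study (temperature loggers, respirometry, repeated point
    counts, habitat plots and parapatric territory mosaics) so every stage
    runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
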