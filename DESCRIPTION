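Package: tactilepop
Title: Population Coding Analysis of Simulated Tactile Afferents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates populations of the three glabrous-skin mechanoreceptive
    afferent classes (SA1, RA, PC) responding to ramp-and-hold probe
    indentations with superimposed vibration, decomposes the population spike
    trains with spatiotemporal non-negative matrix factorization, decodes
    stimulus features from the activation coefficients with an L2-regularized
    multinomial classifier, and quantifies mutual, complementary, and
    redundant information across afferent classes, innervation densities, and
    spatial or temporal perturbations of the spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    nnet,
    pracma,
    readr,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
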