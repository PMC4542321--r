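Package: balnet
Title: Balanced Spiking Networks and Plasticity Models of Orientation Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying orientation selectivity in balanced
    excitatory-inhibitory spiking networks of primary visual cortex layer 2/3.
    Builds networks with either a continuous pinwheel orientation map or a
    salt-and-pepper layout, integrates leaky integrate-and-fire dynamics with
    distance-dependent sparse connectivity, applies multiplicative pair-based
    spike-timing dependent plasticity and a preferred-orientation reconnection
    rule, and analyses the resulting tuning curves (orientation selectivity
    index, population-vector preferred orientation, functional-connectivity
    cosine fits). An analytic mean-field treatment of the equivalent ring
    network predicts balanced-state rates, selectivity, and the stability
    boundary of the balanced state under functional reconnection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    MASS,
    knitr
Config/testthat/edition: 3
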