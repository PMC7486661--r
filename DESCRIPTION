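Package: retwave
Title: Retinal-Wave-Driven Development of Orientation-Specific Cortical
    Horizontal Connections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates Stage II/III spontaneous retinal waves as a
    cellular automaton over ON/OFF retinal ganglion cell mosaics, wires a
    model primary visual cortex through the statistical (dipole) wiring
    model, and develops long-range horizontal connections with a
    covariance-rule Hebbian update driven by wave-evoked responses.
    Includes the accompanying analysis suite: orientation maps and
    similarity maps, Cuzick and Cochran-Armitage trend tests on
    connection weights, windowed Hopkins-statistic clustering indices,
    cross-initialization network similarity, recurrent
    spontaneous-activity generation with seed-pixel correlation maps, and
    wave frequency/direction modulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
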