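Package: bgsdemog
Title: Background Selection and the Inference of Population History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for studying how purifying and
    background selection (BGS) bias demographic inference, and for correcting
    that bias. Provides a forward Wright-Fisher simulator with a discrete
    distribution of fitness effects (DFE) over human-like genome layouts, a
    neutral coalescent engine for calibration, analytical predictions of
    relative diversity (B) and of the expected site frequency spectrum under
    piecewise population-size histories, an SFS model-selection fitter with
    AIC and Akaike weights, and an approximate Bayesian computation (ABC)
    method that treats the DFE as a nuisance parameter so that demographic
    parameters can be estimated even from directly selected sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    readr,
    vcfR,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
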