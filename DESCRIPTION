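Package: concilium
Title: Chemical-Oscillator Network Classifiers for Drug-Response Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of coupled photosensitive Oregonator
    (Belousov-Zhabotinsky) oscillators that classify binary therapy outcomes
    from single-gene expression values. A normalized expression value sets the
    illumination-release time of the network's input oscillator; the readout is
    the number of supra-threshold activator maxima on an output oscillator.
    Networks are trained with an elitist evolutionary algorithm and combined
    into a majority-voting ensemble (a "concilium") to predict multiple-myeloma
    response to bortezomib or dexamethasone. Includes published
    three-oscillator networks and count-to-class rules as fixtures, an
    equal-width-histogram baseline classifier, a synthetic patient-table
    generator, and tidy/ggplot2 interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    deSolve,
    yaml
Config/testthat/edition: 3
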