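Package: spascreen
Title: Semantic-Pointer Neural Simulation of Lexical Medical Screenings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates medical screenings of lexical and cognitive processing
    (picture-induced word naming and word-list repetition) with a large-scale
    semantic-pointer neural model. Semantic pointers are high-dimensional unit
    vectors combined by circular-convolution binding; buffers of leaky
    integrate-and-fire neuron ensembles represent them, associative cleanup
    memories map between lexical levels, and a gated recurrent buffer serves as
    verbal short-term memory. Neuron ablation experiments relate microscopic
    neural deficits to macroscopic behavioural deficits via
    performance-versus-ablation sweep curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
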