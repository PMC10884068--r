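Package: mscomplexity
Title: Complexity Metrics for Categorical (Microstate-Like) Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic and scaling-based complexity analysis of
    symbolic sequences over small finite alphabets, such as EEG microstate
    label sequences. Implements plug-in block entropies with entropy rate and
    excess entropy obtained from a linear fit, Lempel-Ziv (LZ-76) complexity
    rescaled to bits per sample, Hurst exponent estimation by detrended
    fluctuation analysis of signed random-walk embeddings, partial
    autoinformation profiles, first-order Markov surrogate synthesis, and a
    two-dimensional Q-state Potts model Monte-Carlo simulator that serves as
    a ground-truth generator with a known phase transition. Results are
    returned as tidy tibbles ready for plotting and group statistics.
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
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
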