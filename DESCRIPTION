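Package: riboballistic
Title: Ballistic Modeling of Ribosome Densities with mRNA Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models ribosome translation along mRNA as unidirectional
    ballistic transport of point particles coupled to exponential mRNA
    degradation. Provides closed-form probabilities for mRNAs carrying
    exactly k ribosomes (k-somes), per-codon ribosome density profiles for
    k-somes and polysomes, an exact stochastic sampler of the process, a
    continuous-time exclusion-process comparator, and an inverse procedure
    that recovers the initiation rate and per-codon elongation rates from
    monosome and normalized polysome density profiles at a known
    degradation rate. Includes a synthetic benchmark of recovery accuracy
    against the transient-to-stationary density ratio at the start codon,
    and a phase-diagram classification of degradation regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
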