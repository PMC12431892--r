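Package: microdyn
Title: Microstate Dynamics Analysis for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for EEG microstate analysis with an emphasis on temporal
    dynamics. Provides a preprocessing chain (band-pass filtering, epoching,
    iterative bad-channel detection, interpolation, bad-epoch rejection,
    average referencing), global field power peak extraction and filtering,
    polarity-invariant modified k-means clustering of peak topographies with
    multi-start global-explained-variance selection and a three-level
    bootstrap group clustering, back-fitting of group maps by global map
    dissimilarity with window smoothing, and static and dynamic microstate
    markers, map coverage and its entropy, global explained variance, mean
    microstate duration and duration variance, transition matrices, and
    entropy production as a measure of broken detailed balance. A
    synthetic-data generator with planted topographies and Markov dynamics
    makes every stage verifiable by parameter recovery, and nonparametric
    group statistics compare marker distributions across groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
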