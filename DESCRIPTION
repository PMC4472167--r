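Package: alignhmm
Title: Alignment of Paired Time-Course Expression Profiles with Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Aligns pairs of unequal-length time-course gene expression
    profiles with a Gaussian-emission hidden Markov model in which both
    profiles of a pair share one latent state sequence and the shorter
    profile is mapped onto the common state positions through gap-position
    parameters.  Provides pooled Baum-Welch estimation, a robust two-step
    fit (pooled parameter estimate followed by an exhaustive grid search
    over gap positions), full maximum-likelihood fitting of the alignment
    model at fixed gaps, joint and individual Viterbi decoding, aligned
    common representations, Hamming-distance alignment diagnostics with
    ROC evaluation, replicate-averaging and unit-interval scaling
    preprocessing, and a seeded synthetic-data generator for robustness
    experiments with non-alignable (contaminated) profile pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
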