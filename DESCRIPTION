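Package: txsteps
Title: Rate-Limiting Steps in Transcription Initiation from Single-Cell RNA
    Production Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the number and durations of sequential rate-limiting steps
    in transcription initiation from single-cell time series of RNA production.
    Intervals between consecutive RNA appearances in individual cells are
    extracted from movie-like count traces (with division censoring and
    spot-intensity quantization), fitted by maximum likelihood to d-step
    hypoexponential interval models, and compared by likelihood-ratio tests to
    select the smallest adequate number of steps. Includes stochastic
    simulators for the d-step renewal process, movie discretization, spot
    intensities, and a two-state (ON-OFF) promoter, plus parameter-recovery
    power studies that characterize when unequal step durations are
    distinguishable.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
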