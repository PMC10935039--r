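Package: ocuclean
Title: Ocular Artifact Removal from Single-Channel Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes eye-blink and eye-movement (ocular) artifacts from
    single-channel sleep EEG recordings. Contaminated 10-second segments are
    flagged by a support vector machine trained on time-domain, spectral and
    nonlinear features; each flagged segment is decomposed by variational mode
    decomposition (VMD) with mode count and penalty factor tuned by a genetic
    algorithm, the resulting mode stack is unmixed by second-order blind
    identification (SOBI), sources with approximate entropy below a threshold
    are zeroed, and the segment is rebuilt by the inverse transforms. Ships a
    seeded semi-simulated EEG/EOG benchmark generator and the usual denoising
    metrics (correlation, relative RMSE, MSE, PSNR, band-power change, sleep
    staging scores) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
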