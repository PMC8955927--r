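Package: memmixr
Title: Gaussian-Uniform Mixture Modelling of Continuous-Report Memory Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report visual memory experiments in
    which observers report the direction of motion of briefly presented items
    and the dependent measure is the signed report error on (-180, 180]
    degrees. Implements n-Gaussian + uniform mixture densities (n = 1..5) on
    the clipped error domain, analytic reductions of block-diagram memory
    models (sensory memory, attention, short-term memory, guessing) to mixture
    form, maximum-likelihood and cumulative-distribution least-squares fitting
    by multi-start Nelder-Mead, BIC model comparison, a synthetic trial
    generator emulating cue-delay and set-size designs, and an end-to-end
    pipeline extracting intake and precision curves and testing whether
    component standard deviations depend on cue delay.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
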