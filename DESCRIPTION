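Package: uaeopt
Title: Surrogate Modelling and Multi-Objective Optimization of
    Ultrasound-Assisted Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing ultrasound-assisted extraction of bioactive
    compounds from plant by-products. Bundles a 15-run extraction campaign on
    strawberry pomace (three process factors, thirteen bioactivity responses)
    together with published multilayer-perceptron surrogate weights, and
    provides multilayer-perceptron response-surface surrogates with
    multi-restart quasi-Newton training, a formula-defined model validation
    battery (reduced chi-square, RMSE, MBE, MPE, SSE, AARD, r-squared),
    chemometric analyses (pairwise correlation, standardized principal
    component analysis, complete-linkage Manhattan clustering), NSGA-II style
    Pareto optimization over the surrogates, standard-score multi-response
    ranking, and a seeded synthetic campaign generator for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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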