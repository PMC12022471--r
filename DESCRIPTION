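Package: ratiocv
Title: Indirect Within-Subject Biological Variation from Result Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates within-subject biological variation (CV_I) of
    clinical laboratory analytes from routine laboratory information
    system data, without a dedicated sampling study. Consecutive results
    from the same patient are turned into result ratios, a central
    Box-Cox-normal peak is fitted robustly to the contaminated ratio
    distribution, the fitted standard deviation is converted to a total
    coefficient of variation on the Gaussian-ratio or lognormal scale,
    and long-term analytical variation is removed in quadrature.
    Includes percentile-bootstrap confidence intervals, a Monte Carlo
    validation harness for ratio distributions of Gaussian and lognormal
    parents, and a synthetic laboratory-dataset generator with a
    configurable pathological subpopulation for end-to-end testing.
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
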