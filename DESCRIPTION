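Package: twosexlt
Title: Age-Stage Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age-stage, two-sex life tables from individual
    life-history records of laboratory insect cohorts (stage durations,
    sex, adult longevity, daily egg counts) and computes the standard
    demographic parameters: net reproductive rate (R0), gross reproductive
    rate (GRR), the intrinsic rate of increase r solving the Euler-Lotka
    equation, the finite rate of increase lambda = exp(r), and the mean
    generation time T = log(R0)/r. Standard errors are obtained by
    resampling whole individuals with replacement, and treatment groups
    are compared with paired bootstrap tests summarised as a compact
    letter display. A calibrated stochastic cohort generator emulates
    temperature-treatment cohorts so every pipeline stage can be exercised
    and validated without raw rearing data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
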