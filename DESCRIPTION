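Package: sstypes
Title: Sums-of-Squares ANOVA Types and Exact Mixed-Model F-Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact sums-of-squares inference for small designed experiments.
    Implements type 1, 2 and 3 F-tests for unbalanced two-way fixed-effects
    models via generalized-inverse least squares and explicit cell-mean
    contrasts, including the contrast-dependent "type 3" construction that
    popular software produces under reference coding, and re-expresses every
    tested hypothesis as weights on cell means. For balanced randomized
    complete block and split-plot designs it computes stratum sums of squares,
    closed-form unbounded and bounded (non-negative) variance-component
    estimates, the exact F-test for treatment effects, and emulations of the
    denominator degree-of-freedom rules that mixed-model software applies when
    a variance component is estimated at the zero boundary. A Monte-Carlo
    engine estimates type I error rates, boundary probabilities and p-value
    uniformity for each testing strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    lme4,
    lmerTest,
    optparse,
    jsonlite,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
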