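# sstypes

Sums-of-squares ANOVA types and exact mixed-model F-tests for small
designed experiments.

## Why

Two routine analyses give software-dependent p-values, and both traps are
easy to fall into:

- **Unbalanced two-way ANOVA.** With unequal cell counts, type 1, 2 and 3
  F-tests answer different questions. Worse, the construction several
  popular R functions report as "type 3" depends on the factor coding:
  under the default first-level-reference coding it tests equality of two
  cell means *conditional on the first level of the other factor*, not
  equality of marginal means. Results for the same data and "the same
  test" can range from p = 0.49 to p = 0.005.
- **Balanced block experiments at the variance boundary.** When REML
  estimates a block or whole-plot variance as zero, mixed-model software
  switches the denominator of the treatment F-test — and different
  packages pick different denominator degrees of freedom, so their type I
  error rates drift away from the nominal level even though an exact
  sums-of-squares F-test exists.

`sstypes` implements the correct tests and the software variants side by
side, states every tested hypothesis explicitly as weights on cell means,
and measures each strategy's type I error by simulation.

## What it computes

For the saturated two-way model
`y_ijk = mu + alpha_i + beta_j + gamma_ij + e_ijk`, every test is an
estimable contrast `H0: L mu = 0` on the cell means, evaluated as

```
F = (L mu_hat)' { L (X'X)^- L' }^-1 (L mu_hat) / k / sigma_e2_hat,
k = rank(L),  df = (k, n - rank X)
```

with type 1 = frequency-weighted marginal means, type 2 = margins
adjusted for the other factor, type 3 = unweighted marginal means
(Yates's weighted squares of means), and `type3_as_implemented()` = the
contrast-dependent coded-coefficient construction.

For balanced randomized-complete-block and split-plot designs it computes
stratum sums of squares, closed-form unbounded and bounded (non-negative)
variance components, the exact treatment test `F = MS_A / MS_E` (RCB) or
`MS_A / MS_AB` (split-plot) on `(a-1, (a-1)(b-1))` df, and the strategy
emulations `exact` / `nobound` / `sas_default` / `r_lmer` that differ in
denominator and df when the variance estimate hits zero.

## Worked example

The built-in `weight_gain()` data record weight gain for 15 animals in an
unbalanced Sex x Diet layout (cell counts 1, 2, 3 / 3, 3, 3). The three
test types give three different answers for Sex:

```r
library(sstypes)
library(dplyr)

wg <- weight_gain()
anova_tests(wg, "gain", c("Sex", "Diet"), type = c("1", "2", "3")) |>
  filter(term == "Sex")
#> # A tibble: 3 × 8
#>   term  type  scheme    ss   df1   df2 statistic p.value
#>   <chr> <chr> <chr>  <dbl> <int> <int>     <dbl>   <dbl>
#> 1 Sex   1     sum    30.0      1     9    11.0   0.00907
#> 2 Sex   2     sum    10.4      1     9     3.81  0.0828
#> 3 Sex   3     sum     1.41     1     9     0.515 0.491
```

The sequential test (F = 10.96, p = 0.009) compares frequency-weighted
means, the adjusted test (F = 3.81, p = 0.083) removes the Diet margin,
and the marginal-means test (F = 0.52, p = 0.491) weights all six cells
equally — three different questions, three defensible answers. What is
*not* defensible is what the coded-coefficient "type 3" reports under the
default reference coding:

```r
type3_as_implemented(wg, "gain", c("Sex", "Diet"), contrasts = "treatment") |>
  filter(term == "Sex")
#>   term  type  scheme       ss   df1   df2 statistic p.value
#> 1 Sex   3impl treatment  16.3     1     9      5.96  0.0373

hypothesis_weights(wg, "gain", c("Sex", "Diet"), type = "3impl",
                   contrasts = "treatment")
#>   contrast `Female:1` `Female:2` `Female:3` `Male:1` `Male:2` `Male:3`
#> 1        1          1          0          0       -1        0        0
```

F = 5.96 (p = 0.037) is a test of females vs males *on diet 1 only* — the
weight report shows the hypothesis actually tested. Under last-level
reference coding the same call gives F = 13.68 (p = 0.005), conditioning
on diet 3; under sum coding it gives the correct 0.52.

On the mixed side, a split-plot dataset whose whole-plot variance
estimate is negative (`make_fixture("splitplot_boundary")`, a = 3, b = 2,
c = 12) shows the strategies disagreeing:

```r
d <- make_fixture("splitplot_boundary", seed = 1)
mixed_tests(d, "splitplot", treatment = "main", block = "block",
            sub = "sub", response = "y")
#>   strategy    statistic   df1   df2 p.value boundary
#> 1 exact           16.0      2     2  0.0589 TRUE
#> 2 nobound         16.0      2     2  0.0589 TRUE
#> 3 sas_default      3.46     2    35  0.0426 TRUE
#> 4 r_lmer           3.46     2     2  0.224  TRUE
```

Same data, same model: p = 0.059 (exact), 0.043 (pooled denominator with
35 df) or 0.224 (pooled denominator, 2 df). The simulation engine
quantifies what each rule does to the type I error at level 0.05:

```r
grid <- filter(simulation_grid("splitplot"), a == 3, b == 2, sigma_AB2 == 0.1)
type1_error_study(grid, reps = 20000, seed = 1) |>
  select(strategy, rejection, mc_se, boundary_prob)
#>   strategy    rejection   mc_se boundary_prob
#> 1 exact          0.0530 0.00158         0.365
#> 2 nobound        0.0530 0.00158         0.365
#> 3 sas_default    0.0842 0.00196         0.365
#> 4 r_lmer         0.0002 0.00010         0.365
```

The exact test holds its level; the pooled-df rule rejects far too often
(0.084) and the bounded-denominator/exact-df rule almost never (0.0002).
`autoplot()` on a `type1_error_study()` or `pvalue_quantiles()` result
draws the corresponding rate curves and p-value Q-Q plots.

A thin command-line front end over the same functions ships in
`inst/cli/anovatool.R` (subcommands `anova`, `mixed`, `simulate`,
`fixtures`).

## Package layout

- `R/design.R`, `R/fixed-tests.R` — coding schemes, generalized-inverse
  least squares, type 1/2/3 and as-implemented tests, hypothesis weights
- `R/mixed-strata.R`, `R/mixed-varcomp.R`, `R/mixed-tests.R` — stratum
  sums of squares, bounded/unbounded variance components, exact and
  strategy F-tests, Wald statistic
- `R/simulate.R` — generators, chi-square stratum engine, type I error
  and boundary-probability studies, p-value quantiles
- `vignettes/anova-types-and-boundary-strategies.Rmd` — the methods
  vignette: models, assumptions, numerical choices, limitations
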