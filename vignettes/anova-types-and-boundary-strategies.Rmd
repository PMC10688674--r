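---
title: "ANOVA types, estimable hypotheses, and mixed-model tests at the variance boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ANOVA types, estimable hypotheses, and mixed-model tests at the variance boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstypes)
library(dplyr)
```

## The problem

Two seemingly routine analyses produce software-dependent answers:

1. **Unbalanced two-way ANOVA.** When cell counts $n_{ij}$ differ, the
   "type 1", "type 2" and "type 3" F-tests answer three different
   questions, and the popular "type 3" construction used by several R
   functions additionally depends on the contrast coding of the factors.
   Under the default first-level-reference coding it silently tests
   equality of two cell means *conditional on the first level of the other
   factor* instead of equality of marginal means.
2. **Balanced block experiments with a variance component estimated at
   zero.** When the REML estimate of a block or whole-plot variance hits
   the non-negativity boundary, mixed-model software switches the
   denominator of the treatment F-test, and different packages change the
   denominator degrees of freedom differently. The resulting type I error
   rates can be far from nominal even though the design is balanced and an
   exact sums-of-squares F-test exists.

`sstypes` implements both analyses from first principles — generalized-
inverse least squares, explicit estimable hypotheses on cell means, stratum
sums of squares, closed-form bounded/unbounded variance components — plus a
Monte-Carlo engine that measures each strategy's type I error rate.

## The two-way fixed-effects model

The saturated model is
$y_{ijk} = \mu + \alpha_i + \beta_j + \gamma_{ij} + e_{ijk}$ with
$e_{ijk} \sim N(0, \sigma_e^2)$, $i = 1,\dots,a$, $j = 1,\dots,b$,
$k = 1,\dots,n_{ij}$, all cells non-empty. Writing $\mu_{ij}$ for the cell
expectations, every hypothesis of interest is a set of contrasts
$H_0: L\mu = 0$ tested with

$$F = \frac{(L\hat\mu)'\{L(X'X)^-L'\}^{-1}(L\hat\mu) / k}{\hat\sigma_e^2},
\qquad k = \mathrm{rank}(L),$$

referred to $F(k,\, n - \mathrm{rank}\,X)$. On the cell-means
parametrization $X'X$ is diagonal in the $n_{ij}$, the fit is full rank,
and the three test families are fully explicit:

* **type 1** (first factor, entered first) compares the
  frequency-weighted marginal means $\sum_j (n_{ij}/n_{i.})\,\mu_{ij}$;
* **type 2** adjusts each main effect for the other margin; for $a = 2$
  the weights reduce to $n_{1j}n_{2j}/n_{.j}$ per column;
* **type 3** compares unweighted marginal means
  $\bar\mu_{i.} = \sum_j \mu_{ij}/b$ (Yates's weighted squares of means).

Because the type 3 contrast is written directly on cell means, it cannot
depend on any coding scheme. The contrast-*dependent* behaviour of popular
software is reproduced separately by `type3_as_implemented()`, which tests
the term's own coded coefficients: under sum-to-zero coding this coincides
with the correct test, under first/last-level reference coding it is the
conditional test described above.

```{r weights}
wg <- weight_gain()
anova_tests(wg, "gain", c("Sex", "Diet"), type = c("1", "2", "3")) |>
  filter(term == "Sex")
hypothesis_weights(wg, "gain", c("Sex", "Diet"), type = "3impl",
                   contrasts = "treatment")
```

The weight report makes the trap visible: the reference-coded "type 3" of
`Sex` puts weight only on the two Diet-1 cells.

### Numerical choices

* The normal equations are solved with a rank-revealing pseudo-inverse;
  singular values below $10^{-9}$ of the largest are treated as zero. Any
  reflexive g-inverse gives the same estimable functions, so this choice
  is immaterial for every reported quantity (a test verifies invariance
  against an independently computed g-inverse).
* Estimability of each row of $L$ is checked numerically via
  $LG(X'X) = L$ at relative tolerance $10^{-6}$; non-estimable rows are
  errors, not warnings.
* A numerator that is numerically zero (below $10^{-12}$) is reported as
  the computed value with a warning — never rounded to a hard zero, which
  is the software anomaly (F = 0, p = 1) occasionally seen under
  reference codings.
* Factor levels are ordered by first appearance in the data, and
  "first/last level" in the coding schemes refers to that order; the
  conditional tests depend on it, so the ordering rule is part of the
  contract. Level labels are always strings.
* Zero residual df (one observation per cell) is detected by exact
  integer comparison; tests requiring $\hat\sigma_e^2$ then error.
* Term order is fixed at A, B, A:B with A the factor the caller names
  first; only type 1 depends on it.

## Balanced mixed models and the boundary problem

For the randomized complete block design
$y_{ij} = \mu + \alpha_i + b_j + e_{ij}$ with
$b_j \sim N(0, \sigma_B^2)$, the ANOVA strata are $x_A$, $x_B$, $x_E$
with expectations $E[\mathrm{MS}_B] = \sigma_e^2 + a\sigma_B^2$ and
$E[\mathrm{MS}_E] = \sigma_e^2$. The treatment test
$F = \mathrm{MS}_A/\mathrm{MS}_E$ on $(a-1,\,(a-1)(b-1))$ df is exactly
F-distributed and needs no variance estimates. The split-plot design adds
a whole-plot error stratum AB with
$E[\mathrm{MS}_{AB}] = \sigma_e^2 + c\sigma_{AB}^2$, and the main-plot
test is $F = \mathrm{MS}_A/\mathrm{MS}_{AB}$, again on
$(a-1,\,(a-1)(b-1))$ df.

Moment estimation (equal to unconstrained REML here) can give
$\hat\sigma_B^2 < 0$ or $\hat\sigma_{AB}^2 < 0$. Bounded REML then sets
the component to zero and pools its stratum with the residual; the
closed forms in `varcomp_bounded()` reproduce this without an optimizer
(a test checks agreement to $10^{-6}$ against a numerical constrained
REML maximizer). Boundary detection is the closed-form condition
"unbounded estimate $\le 0$", i.e. $\mathrm{MS}_{\text{inner}} \le
\mathrm{MS}_E$; using the exact condition rather than an optimizer's
convergence status removes an ambiguity that the original mixed-model
software itself cannot control. For the split-plot the whole-plot
component is floored first and the block component re-estimated against
the pooled error, iterating until all estimates are non-negative.

`strategy_test()` then emulates what each software reports for the
treatment test when the *innermost* component (block for RCB, whole-plot
for split-plot) is at the boundary:

| strategy | F at boundary | denominator df |
|---|---|---|
| `exact`, `nobound` | $\mathrm{MS}_A/\mathrm{MS}_{E\,\text{or}\,AB}$ | $(a-1)(b-1)$ |
| `sas_default` | $\mathrm{MS}_A/\text{pooled MS}$ | $a(b-1)$ (RCB), $(ac-1)(b-1)$ (split-plot) |
| `r_lmer` | $\mathrm{MS}_A/\text{pooled MS}$ | $(a-1)(b-1)$ |

Away from the boundary all four coincide with the exact test. These df
rules are the behaviour the software exhibits on these balanced designs;
the full Kenward–Roger small-sample algorithm is deliberately **not**
implemented — the rules above are its observed effect here, and
emulating more would be guesswork. For the same reason a negative *block*
component in the split-plot (with a positive whole-plot component) leaves
the main-plot test unchanged: block effects cancel from treatment
contrasts in a balanced design. The `r_lmer` denominator df is fixed at
exactly $(a-1)(b-1)$, resolving the "equal or close to" ambiguity in
favour of the exact value. With fixed block effects the same stratum
arithmetic applies and $\sigma_B^2$ is simply not an estimable component.

```{r boundary}
d <- make_fixture("splitplot_boundary", seed = 1)
mixed_tests(d, "splitplot", treatment = "main", block = "block",
            sub = "sub", response = "y")
```

## The Monte-Carlo engine

`type1_error_study()` estimates each strategy's type I error under the
null (all fixed effects zero, normal random effects). Under these
conditions the stratum sums of squares are independent scaled chi-squares
— $x_B/(\sigma_e^2 + a\sigma_B^2) \sim \chi^2_{b-1}$ and so on — so the
engine samples the stratum mean squares directly from their exact
distributions instead of building data matrices, making 200,000
replicates per case take a fraction of a second. The data-level
generators `gen_rcb()`/`gen_splitplot()` remain first-class: a test
cross-validates the two routes against each other, and they are what
`make_fixture()` and the worked examples use.

The default study conditions are those of the shipped grid
(`simulation_grid()`, 30 RCB + 30 split-plot cases): $\sigma_e^2 = 1$
always; the block variance varies over $0.1,\dots,0.9$ for the RCB model;
for the split-plot model $\sigma_b^2 = 1$ and the whole-plot error
variance varies over $0.1,\dots,0.9$. The default replicate count is
200,000 (Monte-Carlo SE $\approx 0.0005$ at a rate of 0.05); tests and
examples scale it down, and every reported frequency carries its MC
standard error. Per-case RNG substreams are derived from the master seed
and the case index, so per-case results do not depend on which other
cases run. Rejection uses $p < \alpha$ strictly; ties at exactly
$\alpha$ occur with probability zero.

```{r study}
grid <- simulation_grid("splitplot") |> filter(a == 3, b == 2, sigma_AB2 == 0.1)
type1_error_study(grid, reps = 20000, seed = 1) |>
  select(strategy, rejection, mc_se, boundary_prob)
```

The pattern this reproduces: the exact test holds its level by
construction; the pooled-df strategy (`sas_default`) is anti-conservative
at the boundary; the bounded-denominator/exact-df strategy (`r_lmer`) is
severely conservative for small whole-plot variances. The boundary
probability itself has a closed form,
$P\{F(\mathrm{df}_\text{inner}, \mathrm{df}_E) \le \sigma_e^2 /
\mathrm{EMS}_\text{inner}\}$ (`boundary_prob_exact()`), which the
simulation is tested against. `pvalue_quantiles()` plus `autoplot()`
give the corresponding p-value Q-Q plots against $U(0,1)$.

## What the generator does and does not emulate

The generator draws exactly the model the tests assume: independent
normal random effects, homoscedastic errors, complete balanced layouts,
null fixed effects. Passing simulations therefore demonstrate the
arithmetic of the strategies under their own assumptions; they say
nothing about non-normal random effects, unbalanced or incomplete
blocks, or real REML optimizers' convergence behaviour. Two published
columns are known *not* to be reproducible from the stated rules and are
deliberately out of the acceptance surface: the `nobound`-type column in
$\{a = 3, b = 2\}$ layouts (the real KR adjustment deviates slightly
from the exact test there, in a way the stated df rules cannot
express — the sas_default column in that layout inherits part of the
same gap) and the boundary-probability column for very small layouts
(the original optimizer's boundary declarations differ from the
closed-form condition; e.g. published 0.448 vs closed-form 0.471 at
$a = b = 2$, $\sigma_B^2 = 0.1$).

## Known limitations

* Two crossed factors only; no covariates, no empty cells (type 4
  hypotheses), no weighted least squares.
* Mixed-model support is limited to the balanced RCB and split-plot
  designs; no Satterthwaite or full Kenward–Roger df, no unbalanced
  mixed models, no BLUPs.
* `wald_F()` builds the full $n \times n$ covariance matrix and is meant
  for the small experiments this package targets, not large data.
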