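#' Generate balanced block-design data under the null hypothesis
#'
#' `gen_rcb()` draws one observation per (treatment, block) cell from
#' y_ij = b_j + e_ij with b_j ~ N(0, sigma_B2) and e_ij ~ N(0, sigma_e2);
#' `gen_splitplot()` draws y_ijk = b_j + (ab)_ij + e_ijk with
#' (ab)_ij ~ N(0, sigma_AB2). All fixed effects are zero, which is the
#' null-hypothesis configuration of the type I error study. For studies
#' that treat blocks as fixed the block effects are still generated this
#' way (the study design holds sigma_B2 = 1 either way).
#'
#' @param a,b,c Numbers of (main-plot) treatments, blocks and subplot
#'   treatments.
#' @param sigma_B2,sigma_AB2,sigma_e2 Variance components (>= 0).
#' @param seed Optional integer seed; with a seed the output is
#'   reproducible call-for-call.
#' @return A tibble in long format: factor columns (`treatment`, `block`
#'   and, for the split-plot, `main`/`sub`) as character, response `y`.
#' @examples
#' gen_rcb(2, 4, sigma_B2 = 0.5, seed = 1)
#' gen_splitplot(3, 2, 12, sigma_AB2 = 0.1, seed = 1)
#' @export
gen_rcb <- function(a, b, sigma_B2, sigma_e2 = 1, seed = NULL) {
  stopifnot(a >= 2L, b >= 2L, sigma_B2 >= 0, sigma_e2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  bj <- rnorm(b, 0, sqrt(sigma_B2))
  out <- tidyr::expand_grid(treatment = paste0("t", seq_len(a)),
                            block = paste0("b", seq_len(b)))
  out$y <- bj[rep(seq_len(b), a)] + rnorm(a * b, 0, sqrt(sigma_e2))
  out
}

#' @rdname gen_rcb
#' @export
gen_splitplot <- function(a, b, c, sigma_B2 = 1, sigma_AB2, sigma_e2 = 1,
                          seed = NULL) {
  stopifnot(a >= 2L, b >= 2L, c >= 2L,
            sigma_B2 >= 0, sigma_AB2 >= 0, sigma_e2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  bj <- rnorm(b, 0, sqrt(sigma_B2))
  abij <- matrix(rnorm(a * b, 0, sqrt(sigma_AB2)), a, b)
  out <- tidyr::expand_grid(main = paste0("m", seq_len(a)),
                            block = paste0("b", seq_len(b)),
                            sub = paste0("s", seq_len(c)))
  i <- rep(seq_len(a), each = b * c)
  j <- rep(rep(seq_len(b), each = c), a)
  out$y <- bj[j] + abij[cbind(i, j)] + rnorm(a * b * c, 0, sqrt(sigma_e2))
  out
}

# Draw the stratum mean squares needed by the treatment test directly from
# their exact distributions under H0 (Cochran): each stratum SS is an
# independent scaled chi-square, with scale equal to the stratum's expected
# mean square. Returns a list of numeric vectors of length `reps`.
sim_ms <- function(model, a, b, c = NULL, sigma_B2, sigma_AB2 = NULL,
                   sigma_e2 = 1, reps) {
  if (model == "rcb") {
    dfA <- a - 1; dfI <- b - 1; dfE <- (a - 1) * (b - 1)
    lamI <- sigma_e2 + a * sigma_B2
    inner_div <- a
  } else {
    dfA <- a - 1; dfI <- (a - 1) * (b - 1); dfE <- a * (b - 1) * (c - 1)
    lamI <- sigma_e2 + c * sigma_AB2
    inner_div <- c
  }
  lamA <- if (model == "rcb") sigma_e2 else lamI
  list(
    msA = lamA * rchisq(reps, dfA) / dfA,
    msI = lamI * rchisq(reps, dfI) / dfI,
    msE = sigma_e2 * rchisq(reps, dfE) / dfE,
    dfA = dfA, dfI = dfI, dfE = dfE, inner_div = inner_div
  )
}

# Vectorized per-replicate p-values of each strategy given the stratum mean
# squares. The RCB exact test divides MS_A by MS_E; the split-plot exact
# test divides MS_A by MS_AB; both have (a-1)(b-1) denominator df. `msI` is
# the innermost non-residual stratum (B for RCB, AB for split-plot).
strategy_pvalues <- function(model, a, b, c, ms, strategies) {
  dfA <- ms$dfA; dfI <- ms$dfI; dfE <- ms$dfE
  df2_exact <- (a - 1) * (b - 1)
  boundary <- (ms$msI - ms$msE) <= 0
  pooledMS <- (dfI * ms$msI + dfE * ms$msE) / (dfI + dfE)
  if (model == "rcb") {
    F_exact <- ms$msA / ms$msE
    df2_pool <- a * (b - 1)
  } else {
    F_exact <- ms$msA / ms$msI
    df2_pool <- (a * c - 1) * (b - 1)
  }
  p_exact <- pf(F_exact, dfA, df2_exact, lower.tail = FALSE)
  F_bnd <- ifelse(boundary, ms$msA / pooledMS, F_exact)
  pvals <- list(
    exact = p_exact,
    nobound = p_exact,
    sas_default = ifelse(boundary,
                         pf(F_bnd, dfA, df2_pool, lower.tail = FALSE),
                         p_exact),
    r_lmer = ifelse(boundary,
                    pf(F_bnd, dfA, df2_exact, lower.tail = FALSE),
                    p_exact)
  )
  list(p = pvals[strategies], boundary = boundary)
}

sim_case_seed <- function(seed, case) {
  as.integer((as.numeric(seed) * 1000003 + case * 7919) %% 2147483647)
}

#' The simulation grid of the type I error study
#'
#' Returns the full case grid of the study: for the RCB model six layouts
#' {a, b} crossed with block variances 0.1, 0.3, 0.5, 0.7, 0.9 (error
#' variance 1), and for the split-plot model six layouts {a, b, c} crossed
#' with whole-plot error variances 0.1 ... 0.9 (block and subplot error
#' variances 1). The grid ships as a plain-text YAML file in
#' `inst/extdata/simulation_grid.yaml`.
#'
#' @param model `"rcb"`, `"splitplot"` or `"both"`.
#' @return A tibble with columns `model`, `a`, `b`, `c`, `sigma_B2`,
#'   `sigma_AB2`, `sigma_e2` (NA where not applicable).
#' @examples
#' simulation_grid("rcb")
#' @export
simulation_grid <- function(model = c("both", "rcb", "splitplot")) {
  model <- match.arg(model)
  path <- system.file("extdata", "simulation_grid.yaml", package = "sstypes")
  cfg <- yaml::read_yaml(path)
  rows <- purrr::map(cfg$cases, function(cs) {
    vars <- unlist(cs$variance_grid)
    if (cs$model == "rcb") {
      tibble::tibble(model = "rcb", a = cs$a, b = cs$b, c = NA_integer_,
                     sigma_B2 = vars, sigma_AB2 = NA_real_, sigma_e2 = 1)
    } else {
      tibble::tibble(model = "splitplot", a = cs$a, b = cs$b, c = cs$c,
                     sigma_B2 = 1, sigma_AB2 = vars, sigma_e2 = 1)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (model != "both") out <- dplyr::filter(out, .data$model == !!model)
  out
}

#' Monte-Carlo type I error rates of the testing strategies
#'
#' For each case (row of `cases`) simulates `reps` null datasets, applies
#' each strategy's treatment test at level `alpha`, and reports rejection
#' frequencies with their Monte-Carlo standard errors, together with the
#' frequency of a non-positive unbounded estimate of the innermost variance
#' component (the boundary frequency). By default the stratum mean squares
#' are drawn directly from their exact scaled chi-square distributions
#' (valid under H0 for these balanced designs), which makes 200,000
#' replicates per case take well under a second; `method = "data"`
#' generates full data tables through [gen_rcb()] / [gen_splitplot()] and
#' computes the strata from them, for cross-validation at small `reps`.
#'
#' Each case uses its own RNG substream derived from `seed` and the case
#' index, so per-case results do not depend on which other cases are run.
#'
#' @param cases Tibble as returned by [simulation_grid()] (columns `model`,
#'   `a`, `b`, `c`, `sigma_B2`, `sigma_AB2`, `sigma_e2`).
#' @param reps Replicates per case.
#' @param alpha Significance level; rejection is `p < alpha` strictly.
#' @param strategies Character vector of strategies, see [strategy_test()].
#' @param seed Master integer seed.
#' @param method `"strata"` (closed-form stratum sampling) or `"data"`.
#' @return A tibble with one row per case and strategy: the case columns,
#'   `strategy`, `rejection`, `mc_se`, `boundary_prob` and `reps`; class
#'   `ss_sim` for [autoplot()].
#' @examples
#' grid <- dplyr::filter(simulation_grid("rcb"), a == 2, b == 4)
#' type1_error_study(grid, reps = 5000, seed = 1)
#' @export
type1_error_study <- function(cases, reps = 200000, alpha = 0.05,
                              strategies = c("exact", "nobound",
                                             "sas_default", "r_lmer"),
                              seed = 1L, method = c("strata", "data")) {
  method <- match.arg(method)
  strategies <- match.arg(strategies,
                          c("exact", "nobound", "sas_default", "r_lmer"),
                          several.ok = TRUE)
  out <- purrr::map(seq_len(nrow(cases)), function(ci) {
    cs <- cases[ci, ]
    set.seed(sim_case_seed(seed, ci))
    ms <- case_ms(cs, reps, method)
    res <- strategy_pvalues(cs$model, cs$a, cs$b, cs$c, ms, strategies)
    bprob <- mean(res$boundary)
    purrr::map(strategies, function(st) {
      rej <- mean(res$p[[st]] < alpha)
      dplyr::bind_cols(
        cs,
        tibble::tibble(strategy = st, rejection = rej,
                       mc_se = sqrt(rej * (1 - rej) / reps),
                       boundary_prob = bprob, reps = reps))
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  class(out) <- c("ss_sim", class(out))
  out
}

case_ms <- function(cs, reps, method) {
  if (method == "strata") {
    return(sim_ms(cs$model, cs$a, cs$b, cs$c, sigma_B2 = cs$sigma_B2,
                  sigma_AB2 = cs$sigma_AB2, sigma_e2 = cs$sigma_e2,
                  reps = reps))
  }
  # data route: generate full tables and compute the strata from them
  get <- function(d, nm) d$ms[d$stratum == nm]
  if (cs$model == "rcb") {
    draws <- purrr::map(seq_len(reps), function(r) {
      st <- strata_rcb(gen_rcb(cs$a, cs$b, cs$sigma_B2, cs$sigma_e2),
                       "treatment", "block", "y")
      c(get(st, "A"), get(st, "B"), get(st, "E"))
    })
  } else {
    draws <- purrr::map(seq_len(reps), function(r) {
      st <- strata_splitplot(
        gen_splitplot(cs$a, cs$b, cs$c, cs$sigma_B2, cs$sigma_AB2,
                      cs$sigma_e2),
        "main", "block", "sub", "y")
      c(get(st, "A"), get(st, "AB"), get(st, "E"))
    })
  }
  m <- do.call(rbind, draws)
  base <- sim_ms(cs$model, cs$a, cs$b, cs$c, sigma_B2 = cs$sigma_B2,
                 sigma_AB2 = cs$sigma_AB2, sigma_e2 = cs$sigma_e2, reps = 1L)
  list(msA = m[, 1L], msI = m[, 2L], msE = m[, 3L],
       dfA = base$dfA, dfI = base$dfI, dfE = base$dfE,
       inner_div = base$inner_div)
}

#' Boundary probability of the innermost variance component
#'
#' `boundary_prob()` estimates by simulation the probability that the
#' unbounded ANOVA/REML estimate of the innermost non-residual variance
#' component (sigma_B2 for RCB, sigma_AB2 for split-plot) is non-positive.
#' `boundary_prob_exact()` gives the closed form: the estimate is
#' non-positive exactly when the inner-stratum mean square does not exceed
#' the error mean square, a ratio of independent scaled chi-squares, so the
#' probability is P(F(df_inner, df_E) <= sigma_e2 / EMS_inner).
#'
#' @inheritParams type1_error_study
#' @return `boundary_prob()`: the `cases` tibble with `boundary_prob`,
#'   `mc_se` and `reps` columns; `boundary_prob_exact()`: a numeric vector.
#' @examples
#' boundary_prob_exact(tibble::tibble(model = "rcb", a = 2, b = 2,
#'                                    c = NA, sigma_B2 = 0.1,
#'                                    sigma_AB2 = NA, sigma_e2 = 1))
#' @export
boundary_prob <- function(cases, reps = 200000, seed = 1L) {
  purrr::map(seq_len(nrow(cases)), function(ci) {
    cs <- cases[ci, ]
    set.seed(sim_case_seed(seed, ci))
    ms <- sim_ms(cs$model, cs$a, cs$b, cs$c, sigma_B2 = cs$sigma_B2,
                 sigma_AB2 = cs$sigma_AB2, sigma_e2 = cs$sigma_e2,
                 reps = reps)
    p <- mean((ms$msI - ms$msE) <= 0)
    dplyr::bind_cols(cs, tibble::tibble(
      boundary_prob = p, mc_se = sqrt(p * (1 - p) / reps), reps = reps))
  }) |>
    dplyr::bind_rows()
}

#' @rdname boundary_prob
#' @export
boundary_prob_exact <- function(cases) {
  vapply(seq_len(nrow(cases)), function(ci) {
    cs <- cases[ci, ]
    if (cs$model == "rcb") {
      df1 <- cs$b - 1; df2 <- (cs$a - 1) * (cs$b - 1)
      lam <- cs$sigma_e2 + cs$a * cs$sigma_B2
    } else {
      df1 <- (cs$a - 1) * (cs$b - 1); df2 <- cs$a * (cs$b - 1) * (cs$c - 1)
      lam <- cs$sigma_e2 + cs$c * cs$sigma_AB2
    }
    pf(cs$sigma_e2 / lam, df1, df2)
  }, numeric(1))
}

#' Empirical p-value quantiles against the uniform distribution
#'
#' Simulates the null distribution of each strategy's p-value for a single
#' layout and returns the sorted p-values paired with uniform plotting
#' quantiles, ready for a Q-Q plot: a curve above the diagonal means the
#' test is conservative (too many large p-values), below means
#' anti-conservative.
#'
#' @param case One-row tibble as in [type1_error_study()].
#' @param strategies Strategies to include.
#' @param reps Replicates.
#' @param seed Integer seed.
#' @return A tibble of class `ss_pvq`: `strategy`, `p` (sorted), `q_uniform`.
#' @examples
#' cs <- tibble::tibble(model = "splitplot", a = 3, b = 2, c = 12,
#'                      sigma_B2 = 1, sigma_AB2 = 0.1, sigma_e2 = 1)
#' pv <- pvalue_quantiles(cs, reps = 2000, seed = 1)
#' @export
pvalue_quantiles <- function(case, strategies = c("exact", "nobound",
                                                  "sas_default", "r_lmer"),
                             reps = 10000, seed = 1L) {
  stopifnot(nrow(case) == 1L)
  strategies <- match.arg(strategies,
                          c("exact", "nobound", "sas_default", "r_lmer"),
                          several.ok = TRUE)
  set.seed(sim_case_seed(seed, 1L))
  ms <- sim_ms(case$model, case$a, case$b, case$c, sigma_B2 = case$sigma_B2,
               sigma_AB2 = case$sigma_AB2, sigma_e2 = case$sigma_e2,
               reps = reps)
  res <- strategy_pvalues(case$model, case$a, case$b, case$c, ms, strategies)
  out <- purrr::map(strategies, function(st) {
    tibble::tibble(strategy = st, p = sort(res$p[[st]]),
                   q_uniform = stats::ppoints(reps, a = 0.5))
  }) |>
    dplyr::bind_rows()
  class(out) <- c("ss_pvq", class(out))
  out
}
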