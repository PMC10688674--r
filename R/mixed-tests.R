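#' Exact F-test for treatment effects in balanced block designs
#'
#' The sums-of-squares F-test for the null hypothesis of no treatment
#' (RCB) or main-plot treatment (split-plot) effects:
#' F = MS_A / MS_E with (a - 1, (a - 1)(b - 1)) df for the RCB design and
#' F = MS_A / MS_AB with (a - 1, (a - 1)(b - 1)) df for the split-plot
#' design. Under the model this statistic is exactly F-distributed; it uses
#' only sums of squares, so it does not depend on variance-component
#' estimates and is unaffected by boundary issues.
#'
#' @param strata An [strata_rcb()] or [strata_splitplot()] result.
#' @return A one-row tibble: `strategy`, `statistic`, `df1`, `df2`,
#'   `p.value`, `boundary`.
#' @examples
#' exact_F_main(strata_rcb(gen_rcb(2, 4, 0.5, seed = 2),
#'                         "treatment", "block", "y"))
#' @export
exact_F_main <- function(strata) {
  ly <- strata_layout(strata)
  msA <- strata_row(strata, "A")$ms
  den <- strata_row(strata, if (ly$design == "rcb") "E" else "AB")
  if (den$ss <= 0) {
    warn("zero denominator sum of squares; p-value undefined")
    return(tibble::tibble(strategy = "exact", statistic = NA_real_,
                          df1 = ly$a - 1, df2 = den$df, p.value = NA_real_,
                          boundary = NA))
  }
  Fv <- msA / den$ms
  df2 <- (ly$a - 1) * (ly$b - 1)
  tibble::tibble(strategy = "exact", statistic = Fv, df1 = ly$a - 1,
                 df2 = df2,
                 p.value = pf(Fv, ly$a - 1, df2, lower.tail = FALSE),
                 boundary = FALSE)
}

#' Software-strategy F-tests for treatment effects at the variance boundary
#'
#' Computes the treatment (RCB) or main-plot treatment (split-plot) F-test
#' as the four strategies observed across mixed-model software would:
#'
#' * `"exact"`, `"nobound"`: the sums-of-squares test of [exact_F_main()];
#'   allowing negative variance components makes the Wald denominator equal
#'   to the error-stratum mean square, so both use (a - 1)(b - 1)
#'   denominator df.
#' * `"sas_default"`: with the variance component bounded at zero the
#'   denominator becomes the pooled mean square of [varcomp_bounded()] and
#'   the denominator df grow to a(b - 1) (RCB) or (ac - 1)(b - 1)
#'   (split-plot), as if the random term had been dropped from the model;
#'   away from the boundary it equals the exact test.
#' * `"r_lmer"`: the same bounded-denominator F, but the denominator df stay
#'   at the exact value (a - 1)(b - 1).
#'
#' The boundary trigger is a non-positive unbounded estimate of the
#' innermost non-residual component (sigma_B2 for RCB, sigma_AB2 for
#' split-plot).
#'
#' @param strata An [strata_rcb()] or [strata_splitplot()] result.
#' @param strategy Character vector from
#'   `c("exact", "nobound", "sas_default", "r_lmer")`.
#' @return A tibble with one row per strategy: `strategy`, `statistic`,
#'   `df1`, `df2`, `p.value`, `boundary`, plus the variance components used
#'   (`sigma_B2`, `sigma_AB2`, `sigma_e2` where applicable).
#' @examples
#' s <- strata_rcb(make_fixture("rcb_boundary", seed = 1),
#'                 "treatment", "block", "y")
#' strategy_test(s, c("exact", "sas_default", "r_lmer"))
#' @export
strategy_test <- function(strata,
                          strategy = c("exact", "nobound", "sas_default",
                                       "r_lmer")) {
  strategy <- match.arg(strategy, several.ok = TRUE)
  ly <- strata_layout(strata)
  vc_u <- varcomp_unbounded(strata)
  vc_b <- varcomp_bounded(strata)
  inner <- if (ly$design == "rcb") "sigma_B2" else "sigma_AB2"
  at_boundary <- vc_u$estimate[vc_u$component == inner] <= 0
  ex <- exact_F_main(strata)
  msA <- strata_row(strata, "A")$ms
  # bounded-denominator F: MS_A over the error variance of the fixed-effect
  # contrast under the bounded fit (pooled at the boundary)
  den_bounded <- if (ly$design == "rcb") {
    vc_b$estimate[vc_b$component == "sigma_e2"]
  } else {
    vc_b$estimate[vc_b$component == "sigma_e2"] +
      ly$c * vc_b$estimate[vc_b$component == "sigma_AB2"]
  }
  F_bounded <- msA / den_bounded
  df1 <- ly$a - 1
  df2_exact <- (ly$a - 1) * (ly$b - 1)
  df2_pooled <- if (ly$design == "rcb") ly$a * (ly$b - 1) else
    (ly$a * ly$c - 1) * (ly$b - 1)
  one <- function(strat) {
    if (strat %in% c("exact", "nobound") || !at_boundary) {
      out <- ex
    } else {
      df2 <- if (strat == "sas_default") df2_pooled else df2_exact
      out <- tibble::tibble(strategy = strat, statistic = F_bounded,
                            df1 = df1, df2 = df2,
                            p.value = pf(F_bounded, df1, df2,
                                         lower.tail = FALSE),
                            boundary = TRUE)
    }
    out$strategy <- strat
    out$boundary <- at_boundary
    vc <- if (strat %in% c("exact", "nobound")) vc_u else vc_b
    for (i in seq_len(nrow(vc))) out[[vc$component[i]]] <- vc$estimate[i]
    out
  }
  dplyr::bind_rows(lapply(strategy, one))
}

#' One-call mixed-model analysis of a balanced block experiment
#'
#' Builds the stratum table from long-format data and runs
#' [strategy_test()].
#'
#' @param data Long-format data frame.
#' @param design `"rcb"` or `"splitplot"`.
#' @param treatment,block,sub Column names: `treatment` is the (main-plot)
#'   treatment factor, `block` the block factor and `sub` the subplot
#'   factor (split-plot only).
#' @param response Name of the numeric response column.
#' @param blocks `"random"` or `"fixed"` block effects (split-plot only).
#' @param strategy Passed to [strategy_test()].
#' @return The [strategy_test()] tibble.
#' @examples
#' mixed_tests(gen_rcb(2, 4, 0.5, seed = 1), "rcb",
#'             treatment = "treatment", block = "block", response = "y")
#' @export
mixed_tests <- function(data, design = c("rcb", "splitplot"),
                        treatment, block, sub = NULL, response,
                        blocks = "random",
                        strategy = c("exact", "nobound", "sas_default",
                                     "r_lmer")) {
  design <- match.arg(design)
  strata <- if (design == "rcb") {
    strata_rcb(data, treatment, block, response)
  } else {
    if (is.null(sub)) abort("split-plot design requires a subplot factor")
    strata_splitplot(data, treatment, block, sub, response, blocks = blocks)
  }
  strategy_test(strata, strategy)
}

#' Wald-type F-statistic for a mixed-model hypothesis
#'
#' Computes F = (L beta-hat)' (L C-hat L')^{-1} (L beta-hat) / k with
#' beta-hat = (X' V-hat^{-1} X)^- X' V-hat^{-1} Y and
#' C-hat = (X' V-hat^{-1} X)^-, where V-hat = sum_r sigma_r2 Z_r Z_r' +
#' sigma_e2 I is assembled from the supplied variance components and
#' random-effect incidence matrices, and k = rank(L C-hat L'). This is the
#' statistic mixed-model software computes; the denominator df is supplied
#' by the chosen strategy, so only the statistic and numerator df are
#' returned here.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix.
#' @param Z Named list of incidence matrices, one per non-residual variance
#'   component.
#' @param sigma2 Named numeric vector: one entry per element of `Z` plus
#'   `"e"` for the residual variance. Components may be negative (as under
#'   unbounded estimation) provided V-hat stays positive definite.
#' @param L Hypothesis matrix (rows = contrasts on the columns of `X`).
#' @return A one-row tibble: `statistic`, `df1`.
#' @examples
#' d <- gen_rcb(3, 4, 0.5, seed = 9)
#' s <- strata_rcb(d, "treatment", "block", "y")
#' vc <- varcomp_unbounded(s)
#' X <- stats::model.matrix(~ 0 + factor(treatment), d)
#' Z <- list(B = stats::model.matrix(~ 0 + factor(block), d))
#' sig <- c(B = vc$estimate[1], e = vc$estimate[2])
#' L <- cbind(diag(2), -1) # treatment contrasts vs last level
#' wald_F(d$y, X, Z, sig, L)
#' @export
wald_F <- function(y, X, Z, sigma2, L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (!"e" %in% names(sigma2)) abort("sigma2 must contain an 'e' component")
  if (!all(names(Z) %in% names(sigma2))) {
    abort("every Z component needs a matching sigma2 entry")
  }
  n <- length(y)
  V <- diag(sigma2[["e"]], n)
  for (nm in names(Z)) {
    V <- V + sigma2[[nm]] * tcrossprod(as.matrix(Z[[nm]]))
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    neg <- names(sigma2)[sigma2 < 0]
    abort(paste0("V-hat is not positive definite",
                 if (length(neg) > 0L)
                   paste0(" (negative component: ",
                          paste(neg, collapse = ", "), ")")))
  }
  Vi <- chol2inv(chol(V))
  XtVX <- t(X) %*% Vi %*% X
  Ch <- pinv_sym(XtVX)
  beta <- drop(Ch %*% t(X) %*% Vi %*% y)
  M <- L %*% Ch %*% t(L)
  sv <- svd(M)
  k <- sum(sv$d > 1e-9 * max(sv$d, 0))
  if (k < 1L) abort("L C-hat L' has rank zero")
  Mi <- sv$v[, seq_len(k), drop = FALSE] %*%
    (t(sv$u[, seq_len(k), drop = FALSE]) / sv$d[seq_len(k)])
  Lb <- L %*% beta
  Fv <- drop(t(Lb) %*% Mi %*% Lb) / k
  tibble::tibble(statistic = Fv, df1 = k)
}
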