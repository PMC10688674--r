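test_that("the exact test is a pure sums-of-squares statistic", {
  s <- strata_table("splitplot", 3, 2, 12,
                    ms = c(A = 0.356, B = 1, AB = 0.356, E = 0.8775))
  r <- exact_F_main(s)
  expect_equal(r$statistic, 1) # MS_A = MS_AB
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 2)
  s0 <- strata_table("rcb", 2, 3, ms = c(A = 1, B = 1, E = 0))
  expect_warning(r0 <- exact_F_main(s0), "zero denominator")
  expect_true(is.na(r0$p.value))
})

test_that("exact and nobound coincide on every dataset; all strategies
           coincide away from the boundary", {
  set.seed(31)
  for (k in 1:10) {
    d <- gen_splitplot(3, 3, 4, sigma_AB2 = 0.6)
    s <- strata_splitplot(d, "main", "block", "sub", "y")
    r <- strategy_test(s)
    expect_equal(r$statistic[r$strategy == "exact"],
                 r$statistic[r$strategy == "nobound"], tolerance = 1e-12)
    expect_equal(r$p.value[r$strategy == "exact"],
                 r$p.value[r$strategy == "nobound"], tolerance = 1e-12)
    if (!r$boundary[1]) {
      expect_equal(length(unique(round(r$statistic, 10))), 1L)
      expect_equal(length(unique(round(r$df2, 10))), 1L)
    }
  }
})

test_that("the published strategy table is reproduced from its mean squares", {
  # RCB, a = 2, b = 4, boundary dataset with exact F = 5.54
  s1 <- strata_table("rcb", 2, 4,
                     ms = c(A = 5.54 * 0.2996, B = 0.0870, E = 0.2996))
  r1 <- strategy_test(s1)
  get <- function(r, st, col) r[[col]][r$strategy == st]
  expect_equal(get(r1, "exact", "df2"), 3)
  expect_equal(get(r1, "exact", "statistic"), 5.54, tolerance = 1e-3)
  expect_equal(get(r1, "exact", "p.value"), 0.100, tolerance = 1e-2)
  expect_equal(get(r1, "sas_default", "df2"), 6)
  expect_equal(get(r1, "sas_default", "statistic"), 8.58, tolerance = 2e-3)
  expect_equal(get(r1, "sas_default", "p.value"), 0.026, tolerance = 2e-2)
  expect_equal(get(r1, "r_lmer", "df2"), 3)
  expect_equal(get(r1, "r_lmer", "statistic"), 8.58, tolerance = 2e-3)
  expect_equal(get(r1, "r_lmer", "p.value"), 0.061, tolerance = 2e-2)
  # split-plot, a = 3, b = 2, c = 12, boundary dataset with exact F = 22.82
  msB <- 0.3560 + 36 * 15.5005
  s2 <- strata_table("splitplot", 3, 2, 12,
                     ms = c(A = 22.82 * 0.3560, B = msB, AB = 0.3560,
                            E = 0.8775))
  r2 <- strategy_test(s2)
  expect_equal(get(r2, "exact", "df2"), 2)
  expect_equal(get(r2, "exact", "statistic"), 22.82, tolerance = 1e-3)
  expect_equal(get(r2, "exact", "p.value"), 0.042, tolerance = 2e-2)
  expect_equal(get(r2, "sas_default", "df2"), 35)
  expect_equal(get(r2, "sas_default", "statistic"), 9.58, tolerance = 1e-3)
  expect_equal(get(r2, "r_lmer", "df2"), 2)
  expect_equal(get(r2, "r_lmer", "statistic"), 9.58, tolerance = 1e-3)
  expect_equal(get(r2, "r_lmer", "p.value"), 0.094, tolerance = 1e-2)
})

test_that("boundary fixtures diverge between strategies as designed", {
  d <- make_fixture("rcb_boundary", seed = 1)
  r <- mixed_tests(d, "rcb", treatment = "treatment", block = "block",
                   response = "y")
  expect_true(all(r$boundary))
  expect_equal(r$df2[r$strategy == "sas_default"], 2 * 3)
  expect_equal(r$df2[r$strategy == "r_lmer"], 3)
  expect_equal(r$statistic[r$strategy == "sas_default"],
               r$statistic[r$strategy == "r_lmer"])
  dsp <- make_fixture("splitplot_boundary", seed = 1)
  rsp <- mixed_tests(dsp, "splitplot", treatment = "main", block = "block",
                     sub = "sub", response = "y")
  expect_true(all(rsp$boundary))
  expect_equal(rsp$df2[rsp$strategy == "sas_default"], 35)
  expect_equal(rsp$df2[rsp$strategy == "r_lmer"], 2)
})

test_that("the Wald F with stratum variance components recovers the exact F", {
  set.seed(32)
  for (k in 1:5) {
    d <- gen_rcb(3, 4, sigma_B2 = 0.5)
    s <- strata_rcb(d, "treatment", "block", "y")
    vc <- varcomp_unbounded(s)
    m <- rcb_design_matrices(d)
    L <- cbind(diag(2), -1)
    w <- wald_F(m$y, m$X, list(B = m$Zs[[1]]),
                c(B = vc$estimate[vc$component == "sigma_B2"],
                  e = vc$estimate[vc$component == "sigma_e2"]), L)
    ex <- exact_F_main(s)
    expect_equal(w$statistic, ex$statistic, tolerance = 1e-8)
    expect_equal(w$df1, 2)
  }
})

test_that("with a zero block variance the Wald F is the one-way pooled F", {
  d <- gen_rcb(3, 4, sigma_B2 = 0.5, seed = 33)
  s <- strata_rcb(d, "treatment", "block", "y")
  b <- varcomp_bounded(s)
  m <- rcb_design_matrices(d)
  pooled <- (s$ss[s$stratum == "B"] + s$ss[s$stratum == "E"]) /
    (s$df[s$stratum == "B"] + s$df[s$stratum == "E"])
  w <- wald_F(m$y, m$X, list(B = m$Zs[[1]]), c(B = 0, e = pooled),
              cbind(diag(2), -1))
  expect_equal(w$statistic, s$ms[s$stratum == "A"] / pooled,
               tolerance = 1e-8)
})

test_that("the Wald F under bounded components matches the strategy F on a
           boundary split-plot dataset", {
  d <- make_fixture("splitplot_boundary", seed = 4)
  s <- strata_splitplot(d, "main", "block", "sub", "y")
  b <- varcomp_bounded(s)
  est <- setNames(b$estimate, b$component)
  m <- splitplot_design_matrices(d)
  # main-plot marginal mean contrasts over the 3 x 12 cell means; read the
  # main-plot level of each column off the model-matrix column names
  main_of <- sub(".*factor\\(main\\)m([0-9]+).*", "\\1", colnames(m$X))
  Lrow <- function(i1, i2) {
    w <- numeric(ncol(m$X))
    w[main_of == as.character(i1)] <- 1 / 12
    w[main_of == as.character(i2)] <- -1 / 12
    w
  }
  L <- rbind(Lrow(1, 3), Lrow(2, 3))
  w <- wald_F(m$y, m$X, list(B = m$Zs[[1]], AB = m$Zs[[2]]),
              c(B = est[["sigma_B2"]], AB = est[["sigma_AB2"]],
                e = est[["sigma_e2"]]), L)
  r <- strategy_test(s, "r_lmer")
  expect_equal(w$statistic, r$statistic, tolerance = 1e-6)
})

test_that("wald_F refuses a non-positive-definite covariance", {
  d <- gen_rcb(2, 3, sigma_B2 = 0.5, seed = 35)
  m <- rcb_design_matrices(d)
  expect_error(
    wald_F(m$y, m$X, list(B = m$Zs[[1]]), c(B = -2, e = 1),
           matrix(c(1, -1), 1)),
    "not positive definite")
})
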