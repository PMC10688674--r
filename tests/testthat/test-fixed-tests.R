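wg <- weight_gain()

test_that("the weight-gain example reproduces all published F- and p-values", {
  t1 <- type1_tests(wg, "gain", c("Sex", "Diet"))
  expect_equal(t1$statistic[t1$term == "Sex"], 10.9622, tolerance = 1e-4)
  expect_equal(t1$p.value[t1$term == "Sex"], 0.0091, tolerance = 1e-2)
  expect_equal(t1$ss[t1$term == "Sex"], 30.044, tolerance = 1e-4)
  t2 <- type2_tests(wg, "gain", c("Sex", "Diet"))
  expect_equal(t2$statistic[t2$term == "Sex"], 3.8073, tolerance = 1e-4)
  t3 <- type3_correct(wg, "gain", c("Sex", "Diet"))
  expect_equal(t3$statistic[t3$term == "Sex"], 0.5151, tolerance = 1e-3)
  ti <- type3_as_implemented(wg, "gain", c("Sex", "Diet"), "treatment")
  expect_equal(ti$statistic[ti$term == "Sex"], 5.9595, tolerance = 1e-4)
  ts <- type3_as_implemented(wg, "gain", c("Sex", "Diet"), "saslast")
  expect_equal(ts$statistic[ts$term == "Sex"], 13.6824, tolerance = 1e-4)
  tsum <- type3_as_implemented(wg, "gain", c("Sex", "Diet"), "sum")
  expect_equal(tsum$statistic[tsum$term == "Sex"], 0.5151, tolerance = 1e-3)
})

test_that("general_F agrees with direct conditional cell-mean contrasts", {
  fit <- fit_ols(build_design(wg, "gain", c("Sex", "Diet")), "cell")
  # males vs females on the first diet
  r1 <- general_F(fit, c(1, 0, 0, -1, 0, 0))
  expect_equal(r1$statistic, 5.9595, tolerance = 1e-4)
  expect_equal(r1$p.value, 0.0373, tolerance = 1e-3)
  # males vs females on the third diet
  r3 <- general_F(fit, c(0, 0, 1, 0, 0, -1))
  expect_equal(r3$statistic, 13.6824, tolerance = 1e-4)
  expect_equal(r3$p.value, 0.0049, tolerance = 1e-2)
})

test_that("general_F rejects ill-posed hypotheses", {
  fit <- fit_ols(build_design(wg, "gain", c("Sex", "Diet")), "cell")
  # duplicated contrast row -> rank-deficient quadratic form
  L <- rbind(c(1, 0, 0, -1, 0, 0), c(2, 0, 0, -2, 0, 0))
  expect_error(general_F(fit, L), "rank-deficient")
  # a non-estimable row in the rank-deficient coded parametrization
  des <- build_design(wg, "gain", c("Sex", "Diet"), "treatment")
  X_over <- cbind(des$X_cell, 1) # intercept is redundant with the cells
  over <- des
  over$X_cell <- X_over
  fit_over <- fit_ols(over, "cell")
  e_mu11 <- c(1, 0, 0, 0, 0, 0, 1) # intercept + first-cell effect = mu_11
  expect_silent(general_F(fit_over, e_mu11))
  e_bad <- c(0, 0, 0, 0, 0, 0, 1) # the redundant intercept alone is not estimable
  expect_error(general_F(fit_over, e_bad), "non-estimable")
})

test_that("a numerically zero numerator is warned about, not zeroed", {
  d <- balanced_two_way(2, 2, n = 2L)
  # cell means (1, 2, 1, 2): identical rows, but within-cell noise keeps
  # the error variance positive
  d$y <- c(0, 2, 1, 3, 1, 1, 2, 2)
  fit <- fit_ols(build_design(d, "y", c("A", "B")), "cell")
  L <- matrix(c(0.5, 0.5, -0.5, -0.5), 1)
  expect_warning(res <- general_F(fit, L), "numerically zero")
  expect_gte(res$statistic, 0)
  expect_lt(res$statistic, 1e-10)
})

test_that("types coincide on balanced data for every scheme", {
  set.seed(202)
  for (k in 1:4) {
    d <- balanced_two_way(sample(2:3, 1), sample(2:3, 1), n = 2L)
    ref <- type1_tests(d, "y", c("A", "B"))
    for (sc in c("treatment", "sum", "saslast")) {
      for (f in list(type1_tests, type2_tests, type3_correct)) {
        r <- f(d, "y", c("A", "B"), contrasts = sc)
        expect_equal(r$statistic, ref$statistic, tolerance = 1e-8)
      }
    }
    # the coded-coefficient construction coincides only under sum coding:
    # under reference coding it keeps testing the conditional hypothesis,
    # balanced or not
    ri <- type3_as_implemented(d, "y", c("A", "B"), "sum")
    expect_equal(ri$statistic, ref$statistic, tolerance = 1e-8)
  }
})

test_that("the reference-coded construction matches car::Anova even on
           balanced data, where it departs from the marginal test", {
  skip_if_not_installed("car")
  set.seed(207)
  d <- balanced_two_way(2, 3, n = 2L)
  d2 <- d
  d2$A <- factor(d2$A); d2$B <- factor(d2$B)
  ca <- car::Anova(lm(y ~ A * B, d2), type = 3) # contr.treatment default
  ri <- type3_as_implemented(d, "y", c("A", "B"), "treatment")
  expect_equal(ri$statistic[ri$term == "A"], ca["A", "F value"],
               tolerance = 1e-8)
  expect_equal(ri$statistic[ri$term == "B"], ca["B", "F value"],
               tolerance = 1e-8)
})

test_that("types 1, 2 and correct 3 are contrast-invariant; 3impl is not", {
  set.seed(303)
  d <- random_two_way(2, 3)
  for (f in list(type1_tests, type2_tests, type3_correct)) {
    r1 <- f(d, "y", c("A", "B"), contrasts = "treatment")
    r2 <- f(d, "y", c("A", "B"), contrasts = "sum")
    r3 <- f(d, "y", c("A", "B"), contrasts = "saslast")
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
    expect_equal(r1$statistic, r3$statistic, tolerance = 1e-10)
  }
  i_trt <- type3_as_implemented(d, "y", c("A", "B"), "treatment")
  i_sum <- type3_as_implemented(d, "y", c("A", "B"), "sum")
  cor3 <- type3_correct(d, "y", c("A", "B"))
  expect_equal(i_sum$statistic, cor3$statistic, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(i_trt$statistic[1], cor3$statistic[1],
                                tolerance = 1e-4)))
})

test_that("type 2 and type 3 are factor-order invariant; type 1 is not", {
  set.seed(404)
  d <- random_two_way(3, 2)
  for (f in list(type2_tests, type3_correct)) {
    ab <- f(d, "y", c("A", "B"))
    ba <- f(d, "y", c("B", "A"))
    expect_equal(sort(ab$statistic), sort(ba$statistic), tolerance = 1e-9)
  }
  t1_wg_ab <- type1_tests(wg, "gain", c("Sex", "Diet"))
  t1_wg_ba <- type1_tests(wg, "gain", c("Diet", "Sex"))
  expect_equal(t1_wg_ab$statistic[t1_wg_ab$term == "Sex"], 10.9622,
               tolerance = 1e-4)
  expect_false(isTRUE(all.equal(
    t1_wg_ba$statistic[t1_wg_ba$term == "Sex"], 10.9622, tolerance = 1e-3)))
})

test_that("quadratic-form sums of squares match the nested-RSS oracle", {
  set.seed(505)
  for (k in 1:6) {
    d <- random_two_way(sample(2:4, 1), sample(2:4, 1))
    oracle <- ss_by_nested_rss(d)
    t1 <- type1_tests(d, "y", c("A", "B"))
    expect_equal(t1$ss[t1$term == "A"], oracle$t1_A, tolerance = 1e-8)
    expect_equal(t1$ss[t1$term == "B"], oracle$t1_B, tolerance = 1e-8)
    expect_equal(t1$ss[t1$term == "A:B"], oracle$t1_AB, tolerance = 1e-8)
    t2 <- type2_tests(d, "y", c("A", "B"))
    expect_equal(t2$ss[t2$term == "A"], oracle$t2_A, tolerance = 1e-8)
    expect_equal(t2$ss[t2$term == "B"], oracle$t2_B, tolerance = 1e-8)
    # conservation: sequential SS + RSS = total corrected SS
    expect_equal(sum(t1$ss) + oracle$rss, sum((d$y - mean(d$y))^2),
                 tolerance = 1e-8)
  }
})

test_that("type 3 agrees with an established implementation", {
  skip_if_not_installed("car")
  set.seed(606)
  d <- random_two_way(3, 3)
  d2 <- d
  d2$A <- factor(d2$A)
  d2$B <- factor(d2$B)
  m <- lm(y ~ A * B, d2,
          contrasts = list(A = "contr.sum", B = "contr.sum"))
  ca <- car::Anova(m, type = 3)
  t3 <- type3_correct(d, "y", c("A", "B"))
  expect_equal(t3$statistic[t3$term == "A"], ca["A", "F value"],
               tolerance = 1e-8)
  expect_equal(t3$statistic[t3$term == "B"], ca["B", "F value"],
               tolerance = 1e-8)
})

test_that("tested hypotheses re-expressed on cell means match the known forms", {
  w1 <- hypothesis_weights(wg, "gain", c("Sex", "Diet"), "1")
  expect_equal(as.numeric(w1[1, -1]),
               c(1 / 6, 2 / 6, 3 / 6, -1 / 3, -1 / 3, -1 / 3),
               tolerance = 1e-10)
  w2 <- hypothesis_weights(wg, "gain", c("Sex", "Diet"), "2")
  expect_equal(as.numeric(w2[1, -1]),
               c(3 / 4, 6 / 5, 3 / 2, -3 / 4, -6 / 5, -3 / 2),
               tolerance = 1e-10)
  w3 <- hypothesis_weights(wg, "gain", c("Sex", "Diet"), "3")
  expect_equal(as.numeric(w3[1, -1]), c(1, 1, 1, -1, -1, -1) / 3,
               tolerance = 1e-10)
  # reference-coded "type 3" is really a conditional test at one diet
  wi <- hypothesis_weights(wg, "gain", c("Sex", "Diet"), "3impl",
                           contrasts = "treatment")
  expect_equal(as.numeric(wi[1, -1]), c(1, 0, 0, -1, 0, 0),
               tolerance = 1e-8)
  ws <- hypothesis_weights(wg, "gain", c("Sex", "Diet"), "3impl",
                           contrasts = "saslast")
  expect_equal(as.numeric(ws[1, -1]) / max(abs(as.numeric(ws[1, -1]))),
               c(0, 0, 1, 0, 0, -1), tolerance = 1e-8)
  # every weight row is a contrast: it sums to zero
  for (w in list(w1, w2, w3, wi)) {
    expect_equal(sum(as.numeric(w[1, -1])), 0, tolerance = 1e-10)
  }
})
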