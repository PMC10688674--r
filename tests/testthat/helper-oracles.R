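# Shared generators and independent oracles used across the test files.

# random unbalanced two-way table; every cell non-empty
random_two_way <- function(a, b, max_n = 4L, mu = NULL) {
  n <- matrix(sample(seq_len(max_n), a * b, replace = TRUE), a, b)
  if (is.null(mu)) mu <- matrix(rnorm(a * b, sd = 2), a, b)
  rows <- list()
  for (i in seq_len(a)) {
    for (j in seq_len(b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        A = paste0("a", i), B = paste0("b", j),
        y = mu[i, j] + rnorm(n[i, j]))
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# balanced two-way table with n per cell
balanced_two_way <- function(a, b, n = 2L) {
  d <- tidyr::expand_grid(A = paste0("a", seq_len(a)),
                          B = paste0("b", seq_len(b)),
                          rep = seq_len(n))
  d$y <- rnorm(nrow(d))
  d[, c("A", "B", "y")]
}

# sequential (type 1) and adjusted (type 2) sums of squares by brute-force
# RSS differences of nested lm() fits -- independent of the package's
# quadratic-form route
ss_by_nested_rss <- function(data) {
  d <- data
  d$A <- factor(d$A); d$B <- factor(d$B)
  r0 <- deviance(lm(y ~ 1, d))
  rA <- deviance(lm(y ~ A, d))
  rAB <- deviance(lm(y ~ A + B, d))
  rfull <- deviance(lm(y ~ A * B, d))
  rB <- deviance(lm(y ~ B, d))
  list(
    t1_A = r0 - rA, t1_B = rA - rAB, t1_AB = rAB - rfull,
    t2_A = rB - rAB, t2_B = rA - rAB,
    rss = rfull, df = df.residual(lm(y ~ A * B, d))
  )
}

# Constrained REML oracle: maximize the restricted log-likelihood
# -0.5 * (log|V| + log|X'V^-1 X| + y'Py) over the variance components with
# a non-negativity box constraint, using full matrices (no stratum
# shortcuts), so it is independent of the closed-form implementation.
reml_loglik <- function(theta, y, X, Zs) {
  p <- length(theta)
  se2 <- theta[p]
  n <- length(y)
  V <- diag(se2, n)
  for (r in seq_along(Zs)) V <- V + theta[r] * tcrossprod(Zs[[r]])
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(-1e10)
  beta <- chol2inv(ch2) %*% t(X) %*% Vi %*% y
  r <- y - X %*% beta
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
            drop(t(r) %*% Vi %*% r))
}

# analytic REML gradient: dl/dtheta_r = -0.5 (tr(P G_r) - y'P G_r P y)
# with G_r = Z_r Z_r' (or I for the residual) and
# P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1
reml_grad <- function(theta, y, X, Zs) {
  p <- length(theta)
  n <- length(y)
  V <- diag(theta[p], n)
  for (r in seq_along(Zs)) V <- V + theta[r] * tcrossprod(Zs[[r]])
  Vi <- chol2inv(chol(V))
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% chol2inv(chol(XtViX)) %*% t(X) %*% Vi
  Py <- P %*% y
  vapply(seq_len(p), function(r) {
    G <- if (r < p) tcrossprod(Zs[[r]]) else diag(1, n)
    -0.5 * (sum(P * G) - drop(t(Py) %*% G %*% Py))
  }, numeric(1))
}

reml_bounded_oracle <- function(y, X, Zs, start) {
  fits <- lapply(list(start, start * 0.3 + 0.1, start * 3 + 0.05),
                 function(s0) {
    optim(s0, reml_loglik, gr = reml_grad, y = y, X = X, Zs = Zs,
          method = "L-BFGS-B",
          lower = c(rep(0, length(Zs)), 1e-10),
          control = list(fnscale = -1, factr = 1, pgtol = 1e-12,
                         maxit = 1000))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "value"))]]
  best$par
}

rcb_design_matrices <- function(d) {
  list(y = d$y,
       X = model.matrix(~ 0 + factor(treatment), d),
       Zs = list(model.matrix(~ 0 + factor(block), d)))
}

splitplot_design_matrices <- function(d) {
  list(y = d$y,
       X = model.matrix(~ 0 + factor(main):factor(sub), d),
       Zs = list(model.matrix(~ 0 + factor(block), d),
                 model.matrix(~ 0 + factor(main):factor(block), d)))
}
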