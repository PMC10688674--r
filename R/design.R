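#' Factor-level coding matrices
#'
#' Returns the m x (m - 1) coding matrix that maps a factor with `m` levels
#' onto its model columns. `"treatment"` takes the first level as reference
#' (its row is zero), `"saslast"` takes the last level as reference, and
#' `"sum"` is the sigma-restricted coding whose parameters sum to zero over
#' the levels (last row all -1). These are the `contr.treatment`,
#' `contr.SAS` and `contr.sum` conventions.
#'
#' @param levels Character vector of factor levels, in order.
#' @param scheme `"treatment"`, `"sum"` or `"saslast"`.
#' @return A numeric matrix with one row per level.
#' @examples
#' contrast_matrix(c("1", "2", "3"), "sum")
#' @export
contrast_matrix <- function(levels, scheme = c("treatment", "sum", "saslast")) {
  scheme <- match.arg(scheme)
  m <- length(levels)
  if (m < 2L) abort("a factor needs at least two levels to be coded")
  cc <- switch(scheme,
    treatment = stats::contr.treatment(m),
    sum = stats::contr.sum(m),
    saslast = stats::contr.SAS(m)
  )
  dimnames(cc) <- list(levels, paste0(seq_len(m - 1L)))
  cc
}

#' Build design matrices for the two-way interaction model
#'
#' Constructs both parametrizations of the saturated two-way model
#' y_ijk = mu + alpha_i + beta_j + gamma_ij + e_ijk: the full-column-rank
#' coded matrix (intercept, main effects, interaction, under a chosen coding
#' scheme) and the cell-means matrix with one indicator column per (i, j)
#' cell. The two span the same column space; the coded coefficients are an
#' invertible transform of the cell means.
#'
#' @param data Long-format data frame, one row per observation.
#' @param response Name of the numeric response column.
#' @param factors Character vector of the two factor columns, first factor
#'   first (term order is A, B, A:B).
#' @param scheme Coding scheme, see [contrast_matrix()].
#' @return An object of class `ss_design`: a list with the coded matrix
#'   `X_coded`, the cell-means matrix `X_cell`, a `term` label per coded
#'   column, the response `y`, level registries and the cell-count table.
#' @examples
#' build_design(weight_gain(), "gain", c("Sex", "Diet"), "sum")
#' @export
build_design <- function(data, response, factors,
                         scheme = c("treatment", "sum", "saslast")) {
  scheme <- match.arg(scheme)
  tw <- check_two_way(data, response, factors)
  a <- tw$a; b <- tw$b
  ca <- contrast_matrix(tw$levels[[1L]], scheme)
  cb <- contrast_matrix(tw$levels[[2L]], scheme)
  ia <- as.integer(tw$fa)
  ib <- as.integer(tw$fb)
  Xa <- ca[ia, , drop = FALSE]
  Xb <- cb[ib, , drop = FALSE]
  Xab <- matrix(0, nrow(data), (a - 1L) * (b - 1L))
  k <- 0L
  ab_names <- character((a - 1L) * (b - 1L))
  for (p in seq_len(a - 1L)) {
    for (q in seq_len(b - 1L)) {
      k <- k + 1L
      Xab[, k] <- Xa[, p] * Xb[, q]
      ab_names[k] <- paste0(factors[1L], p, ":", factors[2L], q)
    }
  }
  X_coded <- cbind(1, Xa, Xb, Xab)
  rownames(X_coded) <- NULL
  colnames(X_coded) <- c("(Intercept)",
                         paste0(factors[1L], seq_len(a - 1L)),
                         paste0(factors[2L], seq_len(b - 1L)),
                         ab_names)
  term <- c("(Intercept)",
            rep(factors[1L], a - 1L),
            rep(factors[2L], b - 1L),
            rep(paste0(factors[1L], ":", factors[2L]), (a - 1L) * (b - 1L)))
  cell <- (ia - 1L) * b + ib
  X_cell <- matrix(0, nrow(data), a * b)
  X_cell[cbind(seq_len(nrow(data)), cell)] <- 1
  colnames(X_cell) <- as.vector(t(outer(tw$levels[[1L]], tw$levels[[2L]],
                                        paste, sep = ":")))
  structure(
    list(X_coded = X_coded, X_cell = X_cell, term = term, y = tw$y,
         factors = factors, response = response, scheme = scheme,
         levels = tw$levels, n_ij = tw$n_ij, a = a, b = b, cell = cell),
    class = "ss_design")
}

#' @export
print.ss_design <- function(x, ...) {
  cat("<ss_design> two-way interaction model\n")
  cat("  factors:", x$factors[1L], sprintf("(%d levels)", x$a), "x",
      x$factors[2L], sprintf("(%d levels)", x$b), "\n")
  cat("  scheme:", x$scheme, " n =", length(x$y), "\n")
  invisible(x)
}

# Rank-revealing Moore-Penrose pseudo-inverse of a symmetric matrix; singular
# values below rel_tol * max(singular value) are treated as zero. This is a
# reflexive g-inverse, so every estimable function is invariant to it.
pinv_sym <- function(M, rel_tol = 1e-9) {
  s <- svd(M)
  pos <- s$d > rel_tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Generalized-inverse least squares for a built design
#'
#' Solves the (possibly rank-deficient) normal equations with a
#' rank-revealing pseudo-inverse: beta-hat = (X'X)^- X'Y. The residual sum
#' of squares, residual degrees of freedom n - rank(X) and the error-variance
#' estimate follow; fitted cell means are recorded for the saturated model,
#' where they equal the observed cell averages.
#'
#' @param design An [build_design()] result.
#' @param parametrization `"coded"` (default) or `"cell"`; the fit (fitted
#'   values, RSS) is identical, only the parameter vector differs.
#' @return An object of class `ss_fit`: coefficients, the g-inverse of X'X,
#'   `rss`, `df_residual`, `sigma2` (NA when the residual df is zero),
#'   fitted cell means and the design.
#' @examples
#' fit_ols(build_design(weight_gain(), "gain", c("Sex", "Diet"), "sum"))
#' @export
fit_ols <- function(design, parametrization = c("coded", "cell")) {
  stopifnot(inherits(design, "ss_design"))
  parametrization <- match.arg(parametrization)
  X <- if (parametrization == "coded") design$X_coded else design$X_cell
  y <- design$y
  XtX <- crossprod(X)
  G <- pinv_sym(XtX)
  beta <- unname(drop(G %*% crossprod(X, y)))
  fitted <- unname(drop(X %*% beta))
  rss <- sum((y - fitted)^2)
  rk <- sum(svd(XtX)$d > 1e-9 * max(svd(XtX)$d))
  df_res <- length(y) - rk
  sigma2 <- if (df_res == 0L) NA_real_ else rss / df_res
  mu_hat <- vapply(split(design$y, design$cell), mean, numeric(1))
  mu_full <- setNames(
    rep(NA_real_, design$a * design$b),
    as.vector(t(outer(design$levels[[1L]], design$levels[[2L]],
                      paste, sep = ":"))))
  mu_full[as.integer(names(mu_hat))] <- mu_hat
  structure(
    list(coefficients = setNames(beta, colnames(X)), ginv = G, rank = rk,
         rss = rss, df_residual = df_res, sigma2 = sigma2,
         fitted = fitted, cell_means = mu_full,
         parametrization = parametrization, design = design),
    class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat("<ss_fit> generalized-inverse least squares (", x$parametrization,
      " parametrization)\n", sep = "")
  cat(sprintf("  n = %d, rank(X) = %d, RSS = %.4f on %d df, sigma2 = %s\n",
              length(x$fitted), x$rank, x$rss, x$df_residual,
              ifelse(is.na(x$sigma2), "unavailable", sprintf("%.4f", x$sigma2))))
  invisible(x)
}

#' @rdname fit_ols
#' @param x An `ss_fit` object.
#' @param ... Unused.
#' @export
tidy.ss_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname fit_ols
#' @export
glance.ss_fit <- function(x, ...) {
  tibble::tibble(
    nobs = length(x$fitted),
    rank = x$rank,
    rss = x$rss,
    df.residual = x$df_residual,
    sigma2 = x$sigma2
  )
}
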