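#' General F-test of a linear hypothesis on a least-squares fit
#'
#' Tests H0: L beta = 0 with the quadratic-form statistic
#' F = (L beta-hat)' (L (X'X)^- L')^{-1} (L beta-hat) / k / sigma2-hat,
#' where k = rank(L), referred to the F(k, n - rank(X)) distribution.
#' Every row of `L` must be estimable, i.e. lie in the row space of the
#' design matrix; this is checked numerically and a non-estimable row is an
#' error. A numerator that is numerically zero is reported as the computed
#' small value with a warning, never hard-coded to zero.
#'
#' @param fit An [fit_ols()] result.
#' @param L Numeric matrix (or vector, taken as one row) of hypothesis
#'   weights on the parameters of `fit`'s parametrization.
#' @param label Optional label carried into the result.
#' @return A one-row tibble: `term`, `ss`, `df1`, `df2`, `statistic`,
#'   `p.value`.
#' @examples
#' fit <- fit_ols(build_design(weight_gain(), "gain", c("Sex", "Diet")),
#'                parametrization = "cell")
#' L <- matrix(c(1, 0, 0, -1, 0, 0), 1) # mu_11 = mu_21
#' general_F(fit, L)
#' @export
general_F <- function(fit, L, label = "L") {
  stopifnot(inherits(fit, "ss_fit"))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  L <- as.matrix(L)
  if (is.na(fit$sigma2)) {
    abort("error variance is unavailable (zero residual df); cannot test")
  }
  X <- if (fit$parametrization == "coded") fit$design$X_coded else fit$design$X_cell
  if (ncol(L) != ncol(X)) {
    abort(sprintf("L has %d columns but the parametrization has %d parameters",
                  ncol(L), ncol(X)))
  }
  XtX <- crossprod(X)
  G <- fit$ginv
  # estimability: L is in the row space of X iff L (X'X)^- (X'X) = L
  E <- L %*% G %*% XtX
  scale <- pmax(apply(abs(L), 1L, max), 1)
  bad <- which(apply(abs(E - L), 1L, max) > 1e-6 * scale)
  if (length(bad) > 0L) {
    abort(paste0("non-estimable hypothesis row(s): ",
                 paste(bad, collapse = ", ")))
  }
  M <- L %*% G %*% t(L)
  sv <- svd(M)$d
  if (sum(sv > 1e-9 * max(sv, 0)) < nrow(L)) {
    abort("hypothesis matrix is rank-deficient; remove redundant rows")
  }
  k <- nrow(L)
  Lb <- L %*% fit$coefficients
  Q <- drop(t(Lb) %*% solve(M, Lb))
  if (Q < 1e-12) {
    warn("hypothesis numerator is numerically zero; F is reported as computed")
  }
  Fval <- Q / k / fit$sigma2
  tibble::tibble(term = label, ss = Q, df1 = k, df2 = fit$df_residual,
                 statistic = Fval,
                 p.value = pf(Fval, k, fit$df_residual, lower.tail = FALSE))
}

# ---- cell-mean contrast builders --------------------------------------------
# Cells are indexed (i - 1) * b + j for level i of the first factor and level
# j of the second; all hypotheses below are contrasts among the a*b cell
# means mu_ij of the saturated model.

cell_index <- function(a, b) function(i, j) (i - 1L) * b + j

# Type 1 for the first factor: equality of the cell-frequency-weighted
# marginal means (1/n_i.) sum_j n_ij mu_ij.
L_type1_first <- function(n_ij) {
  a <- nrow(n_ij); b <- ncol(n_ij); idx <- cell_index(a, b)
  ni <- rowSums(n_ij)
  L <- matrix(0, a - 1L, a * b)
  for (i in seq_len(a - 1L)) {
    for (j in seq_len(b)) {
      L[i, idx(i, j)] <- n_ij[i, j] / ni[i]
      L[i, idx(a, j)] <- -n_ij[a, j] / ni[a]
    }
  }
  L
}

# Type 2 for the first factor: its margin adjusted for the other factor's
# margin (interaction not adjusted for); the Forward-Doolittle hypothesis
# sum_j n_ij mu_ij = sum_j sum_k n_ij n_kj mu_kj / n_.j.
L_type2_first <- function(n_ij) {
  a <- nrow(n_ij); b <- ncol(n_ij); idx <- cell_index(a, b)
  nj <- colSums(n_ij)
  L <- matrix(0, a - 1L, a * b)
  for (i in seq_len(a - 1L)) {
    for (k in seq_len(a)) {
      for (j in seq_len(b)) {
        L[i, idx(k, j)] <- (k == i) * n_ij[i, j] - n_ij[i, j] * n_ij[k, j] / nj[j]
      }
    }
  }
  L
}

# Type 3 for the first factor: equality of unweighted marginal means
# mu_i. = (1/b) sum_j mu_ij (Yates's weighted squares of means).
L_type3_first <- function(n_ij) {
  a <- nrow(n_ij); b <- ncol(n_ij); idx <- cell_index(a, b)
  L <- matrix(0, a - 1L, a * b)
  for (i in seq_len(a - 1L)) {
    for (j in seq_len(b)) {
      L[i, idx(i, j)] <- 1 / b
      L[i, idx(a, j)] <- -1 / b
    }
  }
  L
}

# Interaction contrasts mu_ij - mu_ib - mu_aj + mu_ab; the highest-order
# term, identical across types 1/2/3.
L_interaction <- function(n_ij) {
  a <- nrow(n_ij); b <- ncol(n_ij); idx <- cell_index(a, b)
  L <- matrix(0, (a - 1L) * (b - 1L), a * b)
  r <- 0L
  for (i in seq_len(a - 1L)) {
    for (j in seq_len(b - 1L)) {
      r <- r + 1L
      L[r, idx(i, j)] <- 1
      L[r, idx(i, b)] <- -1
      L[r, idx(a, j)] <- -1
      L[r, idx(a, b)] <- 1
    }
  }
  L
}

# Transpose the cell ordering so a "first factor" builder serves the second:
# column (i-1)b+j of the result takes the builder's column (j-1)a+i.
swap_cells <- function(L, a, b) {
  L[, as.vector(t(matrix(seq_len(a * b), a, b))), drop = FALSE]
}

cell_fit <- function(data, response, factors) {
  fit_ols(build_design(data, response, factors, "treatment"),
          parametrization = "cell")
}

# ---- the four test families -------------------------------------------------

#' Type 1, 2 and 3 tests for the unbalanced two-way model
#'
#' `type1_tests()` performs the forward sequential analysis (first factor
#' ignoring the second, second adjusted for the first, then interaction);
#' its result depends on the factor order. `type2_tests()` adjusts each main
#' effect for the other main effect but not for the interaction.
#' `type3_correct()` tests equality of the unweighted marginal means,
#' computed on the cell-means parametrization so the result cannot depend on
#' any coding scheme. `type3_as_implemented()` reproduces instead what
#' software that simply tests a term's own coded coefficients reports as
#' "type 3": under sum-to-zero coding this coincides with `type3_correct()`,
#' but under first-level-reference coding it tests equality of the two
#' factor levels *conditional on the first level of the other factor*, and
#' under last-level-reference coding the analogue at the last level.
#'
#' All tests use the error variance of the full interaction model, so the
#' denominator df is n - ab. On balanced data all four families coincide.
#'
#' @param data Long-format data frame.
#' @param response Name of the numeric response column.
#' @param factors Character vector of the two factor columns; the first one
#'   is entered first by the sequential procedure.
#' @param contrasts Coding scheme, see [contrast_matrix()]. Types 1, 2 and
#'   correct type 3 are invariant to it; it is accepted for a uniform
#'   interface (and so the invariance can be demonstrated).
#' @return A tibble with one row per term: `term`, `type`, `scheme`, `ss`,
#'   `df1`, `df2`, `statistic`, `p.value`.
#' @examples
#' type1_tests(weight_gain(), "gain", c("Sex", "Diet"))
#' type3_as_implemented(weight_gain(), "gain", c("Sex", "Diet"), "treatment")
#' @export
type1_tests <- function(data, response, factors, contrasts = "sum") {
  contrasts <- match.arg(contrasts, c("treatment", "sum", "saslast"))
  fit <- cell_fit(data, response, factors)
  n_ij <- fit$design$n_ij
  a <- nrow(n_ij); b <- ncol(n_ij)
  Ls <- list(L_type1_first(n_ij),
             swap_cells(L_type2_first(t(n_ij)), a, b),
             L_interaction(n_ij))
  res <- purrr::map2(Ls, term_labels(factors),
                     function(L, lab) general_F(fit, L, lab))
  dplyr::bind_rows(res) |>
    dplyr::mutate(type = "1", scheme = contrasts, .after = "term")
}

#' @rdname type1_tests
#' @export
type2_tests <- function(data, response, factors, contrasts = "sum") {
  contrasts <- match.arg(contrasts, c("treatment", "sum", "saslast"))
  fit <- cell_fit(data, response, factors)
  n_ij <- fit$design$n_ij
  a <- nrow(n_ij); b <- ncol(n_ij)
  Ls <- list(L_type2_first(n_ij),
             swap_cells(L_type2_first(t(n_ij)), a, b),
             L_interaction(n_ij))
  res <- purrr::map2(Ls, term_labels(factors),
                     function(L, lab) general_F(fit, L, lab))
  dplyr::bind_rows(res) |>
    dplyr::mutate(type = "2", scheme = contrasts, .after = "term")
}

#' @rdname type1_tests
#' @export
type3_correct <- function(data, response, factors, contrasts = "sum") {
  contrasts <- match.arg(contrasts, c("treatment", "sum", "saslast"))
  fit <- cell_fit(data, response, factors)
  n_ij <- fit$design$n_ij
  a <- nrow(n_ij); b <- ncol(n_ij)
  Ls <- list(L_type3_first(n_ij),
             swap_cells(L_type3_first(t(n_ij)), a, b),
             L_interaction(n_ij))
  res <- purrr::map2(Ls, term_labels(factors),
                     function(L, lab) general_F(fit, L, lab))
  dplyr::bind_rows(res) |>
    dplyr::mutate(type = "3", scheme = contrasts, .after = "term")
}

#' @rdname type1_tests
#' @export
type3_as_implemented <- function(data, response, factors,
                                 contrasts = c("treatment", "sum", "saslast")) {
  contrasts <- match.arg(contrasts)
  design <- build_design(data, response, factors, contrasts)
  fit <- fit_ols(design, parametrization = "coded")
  labs <- term_labels(factors)
  p <- ncol(design$X_coded)
  res <- purrr::map(labs, function(lab) {
    cols <- which(design$term == lab)
    L <- matrix(0, length(cols), p)
    L[cbind(seq_along(cols), cols)] <- 1
    general_F(fit, L, lab)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(type = "3impl", scheme = contrasts, .after = "term")
}

term_labels <- function(factors) {
  c(factors[1L], factors[2L], paste0(factors[1L], ":", factors[2L]))
}

#' All ANOVA test families in one table
#'
#' Convenience wrapper running any combination of [type1_tests()],
#' [type2_tests()], [type3_correct()] and [type3_as_implemented()] and
#' binding the results.
#'
#' @inheritParams type1_tests
#' @param type Character vector from `c("1", "2", "3", "3impl")`.
#' @return A tibble, one row per term and type.
#' @examples
#' anova_tests(weight_gain(), "gain", c("Sex", "Diet"),
#'             type = c("1", "2", "3"))
#' @export
anova_tests <- function(data, response, factors,
                        type = c("1", "2", "3"), contrasts = "sum") {
  type <- match.arg(type, c("1", "2", "3", "3impl"), several.ok = TRUE)
  fns <- list(`1` = type1_tests, `2` = type2_tests, `3` = type3_correct,
              `3impl` = type3_as_implemented)
  purrr::map(type, function(tp) {
    fns[[tp]](data, response, factors, contrasts = contrasts)
  }) |>
    dplyr::bind_rows()
}

#' Express a tested hypothesis as weights on cell means
#'
#' Every hypothesis the type 1/2/3 machinery tests is a set of contrasts
#' among the a*b cell means mu_ij. This function returns those weights
#' explicitly, which is the clearest way to see *what question* each test
#' answers on unbalanced data: type 1 weights cells by their frequencies
#' n_ij / n_i., type 2 by the margin products n_ij n_kj / n_.j, and type 3
#' equally by 1/b. For `type = "3impl"` the coded-coefficient hypothesis is
#' mapped back onto cell means (the coded parameters are an invertible
#' transform of the cell means) and each row is scaled so the weights over
#' the first factor level's cells sum to one where that block is nonzero.
#'
#' @inheritParams type1_tests
#' @param type One of `"1"`, `"2"`, `"3"`, `"3impl"`.
#' @param term Which term's hypothesis to report; defaults to the first
#'   factor.
#' @return A tibble with a `contrast` index and one numeric column per cell,
#'   named `<levelA>:<levelB>`.
#' @examples
#' hypothesis_weights(weight_gain(), "gain", c("Sex", "Diet"), type = "2")
#' @export
hypothesis_weights <- function(data, response, factors,
                               type = c("1", "2", "3", "3impl"),
                               term = factors[1L],
                               contrasts = "treatment") {
  type <- match.arg(type)
  contrasts <- match.arg(contrasts, c("treatment", "sum", "saslast"))
  design <- build_design(data, response, factors, contrasts)
  n_ij <- design$n_ij
  a <- nrow(n_ij); b <- ncol(n_ij)
  labs <- term_labels(factors)
  if (!term %in% labs) abort(paste0("unknown term: ", term))
  W <- if (type == "3impl") {
    # unique-cell coded matrix T maps cell means to coded parameters:
    # mu = T beta with T invertible (ab columns, ab cells), so
    # L beta = (L T^{-1}) mu.
    Tm <- unique_cell_coded(design)
    cols <- which(design$term == term)
    L <- matrix(0, length(cols), ncol(design$X_coded))
    L[cbind(seq_along(cols), cols)] <- 1
    Wr <- L %*% solve(Tm)
    t(apply(Wr, 1L, normalize_weight_row, a = a, b = b, term = term,
            first_factor = labs[1L]))
  } else {
    first <- switch(type, `1` = L_type1_first, `2` = L_type2_first,
                    `3` = L_type3_first)
    if (term == labs[1L]) {
      first(n_ij)
    } else if (term == labs[2L]) {
      swap_cells(first(t(n_ij)), a, b)
    } else {
      L_interaction(n_ij)
    }
  }
  W <- matrix(as.numeric(W), nrow = nrow(W),
              dimnames = list(NULL, colnames(design$X_cell)))
  out <- tibble::as_tibble(W)
  dplyr::bind_cols(tibble::tibble(contrast = seq_len(nrow(out))), out)
}

# coded design rows for the a*b unique cells, in cell-index order
unique_cell_coded <- function(design) {
  ord <- order(design$cell)
  first <- ord[!duplicated(design$cell[ord])]
  design$X_coded[first, , drop = FALSE]
}

normalize_weight_row <- function(w, a, b, term, first_factor) {
  w[abs(w) < 1e-10] <- 0
  block1 <- sum(w[seq_len(b)])
  if (abs(block1) > 1e-10) return(w / block1)
  nz <- which(w != 0)[1L]
  if (is.na(nz)) w else w / abs(w[nz]) * sign(w[nz])
}
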