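#' The unbalanced weight-gain experiment
#'
#' A two-factor feeding experiment on fifteen animals: weight gain after one
#' of three diets, recorded separately for females and males. The layout is
#' unbalanced (cell counts 1, 2, 3 in the female row and 3, 3, 3 in the male
#' row), which is what makes the type 1, 2 and 3 tests of `Sex` answer three
#' different questions.
#'
#' @return A tibble with 15 rows and columns `Sex` (`"Female"`/`"Male"`),
#'   `Diet` (`"1"`, `"2"`, `"3"`, a label, not a number) and numeric `gain`.
#' @examples
#' weight_gain()
#' @export
weight_gain <- function() {
  tibble::tibble(
    Sex = rep(c("Female", "Male"), c(6L, 9L)),
    Diet = c("1", "2", "2", "3", "3", "3",
             "1", "1", "1", "2", "2", "2", "3", "3", "3"),
    gain = c(10, 19, 21, 23, 22, 25,
             13, 17, 14, 18, 20, 17, 17, 18, 20)
  )
}

#' Built-in and synthetic example datasets
#'
#' `make_fixture()` returns small datasets used throughout the documentation
#' and tests: the weight-gain table, a balanced 2x2 layout on which all test
#' types coincide, and seeded synthetic RCB / split-plot datasets constructed
#' (by rejection sampling) to have a negative unbounded estimate of the
#' innermost variance component, so that the boundary-dependent testing
#' strategies actually diverge on them.
#'
#' @param name One of `"table1"`, `"balanced_2x2"`, `"rcb_boundary"`,
#'   `"splitplot_boundary"`.
#' @param seed Integer seed for the synthetic fixtures (ignored for the
#'   deterministic ones).
#' @return A tibble in long format; factor columns are character.
#' @examples
#' make_fixture("balanced_2x2")
#' fx <- make_fixture("rcb_boundary", seed = 3)
#' @export
make_fixture <- function(name = c("table1", "balanced_2x2", "rcb_boundary",
                                  "splitplot_boundary"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    table1 = weight_gain(),
    balanced_2x2 = tibble::tibble(
      A = rep(c("a1", "a2"), each = 4L),
      B = rep(rep(c("b1", "b2"), each = 2L), 2L),
      y = c(1.2, 0.8, 2.1, 1.9, 3.0, 3.4, 4.1, 3.7)
    ),
    rcb_boundary = {
      a <- 2L; b <- 4L
      for (k in seq_len(1000L)) {
        d <- gen_rcb(a, b, sigma_B2 = 0.1, sigma_e2 = 1, seed = seed + 7919L * k)
        vc <- varcomp_unbounded(strata_rcb(d, "treatment", "block", "y"))
        if (vc$estimate[vc$component == "sigma_B2"] < 0) return(d)
      }
      abort("no boundary RCB dataset found in 1000 attempts")  # nocov
    },
    splitplot_boundary = {
      a <- 3L; b <- 2L; c_ <- 12L
      for (k in seq_len(1000L)) {
        d <- gen_splitplot(a, b, c_, sigma_B2 = 1, sigma_AB2 = 0.1,
                           sigma_e2 = 1, seed = seed + 7919L * k)
        vc <- varcomp_unbounded(
          strata_splitplot(d, "main", "block", "sub", "y"))
        if (vc$estimate[vc$component == "sigma_AB2"] < 0) return(d)
      }
      abort("no boundary split-plot dataset found in 1000 attempts")  # nocov
    }
  )
}

#' Read a long-format experiment table from CSV
#'
#' Reads a comma-separated file with a header row, one row per observation,
#' one column per factor and one numeric response column. Factor levels are
#' kept as character strings (the diet label `"1"`, never the number 1) and
#' their order of first appearance in the file defines the level order that
#' reference codings refer to.
#'
#' @param path Path to a CSV file.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names, in model order
#'   (the first factor is the one entered first by the sequential type 1 test).
#' @return A tibble with the factor columns (character) and the response.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' utils::write.csv(weight_gain(), tf, row.names = FALSE)
#' read_experiment(tf, "gain", c("Sex", "Diet"))
#' @export
read_experiment <- function(path, response, factors) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0L) abort(paste0("empty file: ", path))
  missing_cols <- setdiff(c(response, factors), names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  y <- suppressWarnings(as.numeric(raw[[response]]))
  bad <- which(!is.finite(y))
  if (length(bad) > 0L) {
    abort(paste0("non-numeric or missing response '", response,
                 "' in row(s): ", paste(utils::head(bad, 5L), collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[, factors, drop = FALSE])
  out[[response]] <- y
  out
}

# Validate a two-way table and collect its level registry and cell counts.
# Levels are ordered by first appearance unless the column is already a factor.
check_two_way <- function(data, response, factors) {
  if (length(factors) != 2L) {
    abort("exactly two factors are required for the two-way model")
  }
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("column(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    abort(paste0("response '", response, "' must be finite numeric"))
  }
  levs <- lapply(factors, function(f) {
    x <- data[[f]]
    lv <- if (is.factor(x)) levels(x) else unique(as.character(x))
    if (length(lv) < 2L) {
      abort(paste0("factor '", f, "' has a single level; no contrasts exist"))
    }
    lv
  })
  names(levs) <- factors
  fa <- factor(as.character(data[[factors[1L]]]), levels = levs[[1L]])
  fb <- factor(as.character(data[[factors[2L]]]), levels = levs[[2L]])
  n_ij <- table(fa, fb)
  if (any(n_ij == 0L)) {
    abort("every (i, j) cell must contain at least one observation")
  }
  list(y = y, fa = fa, fb = fb, levels = levs, n_ij = unclass(n_ij),
       a = length(levs[[1L]]), b = length(levs[[2L]]))
}
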