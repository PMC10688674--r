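#' Stratum sums of squares for a balanced randomized complete block design
#'
#' Decomposes a balanced RCB response (one observation per treatment x block
#' combination) into its three ANOVA strata: treatments (A), blocks (B) and
#' residual (E), with degrees of freedom a - 1, b - 1 and (a - 1)(b - 1) and
#' the expected-mean-square coefficients E[MS_B] = sigma_e2 + a sigma_B2,
#' E[MS_E] = sigma_e2. The three sums of squares add up to the total
#' corrected sum of squares.
#'
#' @param data Long-format data frame with one row per observation.
#' @param treatment,block Names of the treatment and block factor columns.
#' @param response Name of the numeric response column.
#' @return An `ss_strata` tibble with columns `stratum`, `ss`, `df`, `ms`
#'   and the EMS coefficients `c_e`, `c_AB`, `c_B`; the layout is stored as
#'   an attribute.
#' @examples
#' d <- gen_rcb(3, 4, sigma_B2 = 0.5, seed = 1)
#' strata_rcb(d, "treatment", "block", "y")
#' @export
strata_rcb <- function(data, treatment, block, response) {
  cols <- c(treatment, block, response)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    abort(paste0("column(s) not found: ", paste(miss, collapse = ", ")))
  }
  ti <- factor(as.character(data[[treatment]]))
  bj <- factor(as.character(data[[block]]))
  y <- data[[response]]
  a <- nlevels(ti); b <- nlevels(bj)
  counts <- table(ti, bj)
  if (any(counts != 1L)) {
    abort("RCB layout requires exactly one observation per (treatment, block) cell")
  }
  Y <- matrix(0, a, b)
  Y[cbind(as.integer(ti), as.integer(bj))] <- y
  gi <- rowMeans(Y); gj <- colMeans(Y); g <- mean(Y)
  xA <- b * sum((gi - g)^2)
  xB <- a * sum((gj - g)^2)
  xE <- sum((Y - outer(gi, rep(1, b)) - outer(rep(1, a), gj) + g)^2)
  out <- tibble::tibble(
    stratum = c("A", "B", "E"),
    ss = c(xA, xB, xE),
    df = c(a - 1, b - 1, (a - 1) * (b - 1)),
    ms = .data$ss / .data$df,
    c_e = c(1, 1, 1),
    c_AB = c(0, 0, 0),
    c_B = c(0, a, 0)
  )
  new_strata(out, list(design = "rcb", a = a, b = b, blocks = "random"))
}

#' Stratum sums of squares for a balanced split-plot design
#'
#' Decomposes a balanced split-plot response (one observation per
#' main-plot treatment i, block j, subplot treatment k) into six strata:
#' main-plot treatments (A), blocks (B), whole-plot error (AB), subplot
#' treatments (C), interaction (AC) and residual (E). Expected mean squares:
#' E[MS_AB] = sigma_e2 + c sigma_AB2, E[MS_B] = sigma_e2 + c sigma_AB2 +
#' ac sigma_B2 (random blocks) and E[MS_E] = sigma_e2. With fixed block
#' effects the arithmetic is identical but sigma_B2 is not an estimable
#' component.
#'
#' @param data Long-format data frame.
#' @param main,block,sub Names of the main-plot treatment, block and subplot
#'   treatment columns.
#' @param response Name of the numeric response column.
#' @param blocks `"random"` or `"fixed"` block effects.
#' @return An `ss_strata` tibble as in [strata_rcb()], six rows.
#' @examples
#' d <- gen_splitplot(3, 2, 4, sigma_B2 = 1, sigma_AB2 = 0.3, seed = 1)
#' strata_splitplot(d, "main", "block", "sub", "y")
#' @export
strata_splitplot <- function(data, main, block, sub, response,
                             blocks = c("random", "fixed")) {
  blocks <- match.arg(blocks)
  cols <- c(main, block, sub, response)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    abort(paste0("column(s) not found: ", paste(miss, collapse = ", ")))
  }
  fi <- factor(as.character(data[[main]]))
  fj <- factor(as.character(data[[block]]))
  fk <- factor(as.character(data[[sub]]))
  y <- data[[response]]
  a <- nlevels(fi); b <- nlevels(fj); cc <- nlevels(fk)
  if (any(table(fi, fj, fk) != 1L)) {
    abort("split-plot layout requires exactly one observation per (main, block, sub) cell")
  }
  Y <- array(0, c(a, b, cc))
  Y[cbind(as.integer(fi), as.integer(fj), as.integer(fk))] <- y
  g <- mean(Y)
  mi <- apply(Y, 1L, mean); mj <- apply(Y, 2L, mean); mk <- apply(Y, 3L, mean)
  mij <- apply(Y, c(1L, 2L), mean)
  mik <- apply(Y, c(1L, 3L), mean)
  xA <- b * cc * sum((mi - g)^2)
  xB <- a * cc * sum((mj - g)^2)
  xAB <- cc * sum((mij - outer(mi, rep(1, b)) - outer(rep(1, a), mj) + g)^2)
  xC <- a * b * sum((mk - g)^2)
  xAC <- b * sum((mik - outer(mi, rep(1, cc)) - outer(rep(1, a), mk) + g)^2)
  tot <- sum((Y - g)^2)
  xE <- tot - xA - xB - xAB - xC - xAC
  out <- tibble::tibble(
    stratum = c("A", "B", "AB", "C", "AC", "E"),
    ss = c(xA, xB, xAB, xC, xAC, xE),
    df = c(a - 1, b - 1, (a - 1) * (b - 1), cc - 1,
           (a - 1) * (cc - 1), a * (b - 1) * (cc - 1)),
    ms = .data$ss / .data$df,
    c_e = rep(1, 6L),
    c_AB = c(0, cc, cc, 0, 0, 0),
    c_B = c(0, a * cc, 0, 0, 0, 0)
  )
  new_strata(out, list(design = "splitplot", a = a, b = b, c = cc,
                       blocks = blocks))
}

#' Build a stratum table from published mean squares
#'
#' Constructs the same object as [strata_rcb()] / [strata_splitplot()]
#' directly from per-stratum mean squares, so that variance-component and
#' strategy arithmetic can be applied to an ANOVA table taken from a report
#' rather than raw data. Strata not supplied (for the split-plot, the
#' subplot strata C and AC, which the treatment test never uses) are filled
#' with zero sums of squares.
#'
#' @param design `"rcb"` or `"splitplot"`.
#' @param a,b,c Layout dimensions.
#' @param ms Named numeric vector of mean squares, names among
#'   `"A"`, `"B"`, `"E"` (RCB) or `"A"`, `"B"`, `"AB"`, `"C"`, `"AC"`,
#'   `"E"` (split-plot).
#' @param blocks `"random"` or `"fixed"` (split-plot only).
#' @return An `ss_strata` tibble.
#' @examples
#' strata_table("rcb", a = 2, b = 4, ms = c(A = 1.66, B = 0.087, E = 0.2996))
#' @export
strata_table <- function(design = c("rcb", "splitplot"), a, b, c = NULL,
                         ms, blocks = "random") {
  design <- match.arg(design)
  if (design == "rcb") {
    strata <- c("A", "B", "E")
    df <- c(a - 1, b - 1, (a - 1) * (b - 1))
    c_e <- rep(1, 3L); c_AB <- rep(0, 3L); c_B <- c(0, a, 0)
    ly <- list(design = "rcb", a = a, b = b, blocks = "random")
  } else {
    if (is.null(c)) abort("split-plot layout requires c")
    strata <- c("A", "B", "AB", "C", "AC", "E")
    df <- c(a - 1, b - 1, (a - 1) * (b - 1), c - 1,
            (a - 1) * (c - 1), a * (b - 1) * (c - 1))
    c_e <- rep(1, 6L); c_AB <- c(0, c, c, 0, 0, 0)
    c_B <- c(0, a * c, 0, 0, 0, 0)
    ly <- list(design = "splitplot", a = a, b = b, c = c,
               blocks = match.arg(blocks, c("random", "fixed")))
  }
  unknown <- setdiff(names(ms), strata)
  if (length(unknown) > 0L) {
    abort(paste0("unknown stratum name(s): ", paste(unknown, collapse = ", ")))
  }
  msv <- setNames(rep(0, length(strata)), strata)
  msv[names(ms)] <- ms
  out <- tibble::tibble(stratum = strata, ss = unname(msv) * df, df = df,
                        ms = unname(msv), c_e = c_e, c_AB = c_AB, c_B = c_B)
  new_strata(out, ly)
}

new_strata <- function(tbl, layout) {
  structure(tbl, layout = layout, class = c("ss_strata", class(tbl)))
}

#' @export
print.ss_strata <- function(x, ...) {
  ly <- attr(x, "layout")
  cat("<ss_strata> ", ly$design, " design, a = ", ly$a, ", b = ", ly$b,
      if (!is.null(ly$c)) paste0(", c = ", ly$c), ", ", ly$blocks,
      " blocks\n", sep = "")
  NextMethod()
}

strata_layout <- function(strata) {
  ly <- attr(strata, "layout")
  if (is.null(ly)) abort("not an ss_strata object (missing layout)")
  ly
}

strata_row <- function(strata, name) {
  i <- match(name, strata$stratum)
  if (is.na(i)) abort(paste0("stratum not present: ", name))
  strata[i, ]
}
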