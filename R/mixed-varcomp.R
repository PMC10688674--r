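#' Closed-form variance-component estimates for balanced designs
#'
#' `varcomp_unbounded()` equates the observed stratum mean squares to their
#' expectations (the ANOVA / method-of-moments estimators, which coincide
#' with unconstrained REML for these balanced designs):
#' RCB: sigma_B2 = (MS_B - MS_E) / a, sigma_e2 = MS_E; split-plot:
#' sigma_AB2 = (MS_AB - MS_E) / c, sigma_B2 = (MS_B - MS_AB) / (ac),
#' sigma_e2 = MS_E. Negative estimates are returned as they are.
#'
#' `varcomp_bounded()` imposes the non-negativity constraint the way REML
#' with a zero lower bound resolves it on these designs: when the innermost
#' non-residual component comes out non-positive it is set to zero and its
#' stratum is pooled with the residual, sigma_e2 = (SS_inner + SS_E) /
#' (df_inner + df_E); remaining components are then re-estimated against the
#' pooled error and floored in turn (with further pooling) until all are
#' non-negative.
#'
#' @param strata An [strata_rcb()] or [strata_splitplot()] result.
#' @return A tibble with columns `component` (`"sigma_B2"`, `"sigma_AB2"`,
#'   `"sigma_e2"` as applicable), `estimate` and logical `boundary`;
#'   attribute `bounded` records which estimator was used.
#' @examples
#' s <- strata_rcb(gen_rcb(2, 4, sigma_B2 = 0.1, seed = 4),
#'                 "treatment", "block", "y")
#' varcomp_unbounded(s)
#' varcomp_bounded(s)
#' @export
varcomp_unbounded <- function(strata) {
  ly <- strata_layout(strata)
  ms <- setNames(strata$ms, strata$stratum)
  est <- if (ly$design == "rcb") {
    c(sigma_B2 = (ms[["B"]] - ms[["E"]]) / ly$a, sigma_e2 = ms[["E"]])
  } else if (ly$blocks == "random") {
    c(sigma_B2 = (ms[["B"]] - ms[["AB"]]) / (ly$a * ly$c),
      sigma_AB2 = (ms[["AB"]] - ms[["E"]]) / ly$c,
      sigma_e2 = ms[["E"]])
  } else {
    c(sigma_AB2 = (ms[["AB"]] - ms[["E"]]) / ly$c, sigma_e2 = ms[["E"]])
  }
  structure(
    tibble::tibble(component = names(est), estimate = unname(est),
                   boundary = c(est[-length(est)] <= 0, FALSE)),
    bounded = FALSE, layout = ly, class = c("ss_varcomp", class(tibble::tibble())))
}

#' @rdname varcomp_unbounded
#' @export
varcomp_bounded <- function(strata) {
  ly <- strata_layout(strata)
  ss <- setNames(strata$ss, strata$stratum)
  df <- setNames(strata$df, strata$stratum)
  ms <- setNames(strata$ms, strata$stratum)
  if (ly$design == "rcb") {
    sB <- (ms[["B"]] - ms[["E"]]) / ly$a
    if (sB <= 0) {
      est <- c(sigma_B2 = 0,
               sigma_e2 = (ss[["B"]] + ss[["E"]]) / (df[["B"]] + df[["E"]]))
      bnd <- c(TRUE, FALSE)
    } else {
      est <- c(sigma_B2 = sB, sigma_e2 = ms[["E"]])
      bnd <- c(FALSE, FALSE)
    }
  } else {
    # split-plot: floor sigma_AB2 first (innermost), then sigma_B2,
    # re-pooling after each flooring
    pool <- function(...) {
      nm <- c(...)
      sum(ss[nm]) / sum(df[nm])
    }
    sAB <- (ms[["AB"]] - ms[["E"]]) / ly$c
    bnd_AB <- sAB <= 0
    bnd_B <- FALSE
    if (bnd_AB) {
      sAB_b <- 0
      sE <- pool("AB", "E")
      sB_b <- (ms[["B"]] - sE) / (ly$a * ly$c)
      if (ly$blocks == "random" && sB_b <= 0) {
        bnd_B <- TRUE
        sB_b <- 0
        sE <- pool("B", "AB", "E")
      }
    } else {
      sAB_b <- sAB
      sE <- ms[["E"]]
      sB_b <- (ms[["B"]] - ms[["AB"]]) / (ly$a * ly$c)
      if (ly$blocks == "random" && sB_b <= 0) {
        # only the outer component at the boundary: pool B into AB
        bnd_B <- TRUE
        sB_b <- 0
        sAB_b <- (pool("B", "AB") - ms[["E"]]) / ly$c
        if (sAB_b <= 0) {
          bnd_AB <- TRUE
          sAB_b <- 0
          sE <- pool("B", "AB", "E")
        }
      }
    }
    if (ly$blocks == "random") {
      est <- c(sigma_B2 = sB_b, sigma_AB2 = sAB_b, sigma_e2 = sE)
      bnd <- c(bnd_B, bnd_AB, FALSE)
    } else {
      est <- c(sigma_AB2 = sAB_b, sigma_e2 = sE)
      bnd <- c(bnd_AB, FALSE)
    }
  }
  structure(
    tibble::tibble(component = names(est), estimate = unname(est),
                   boundary = bnd),
    bounded = TRUE, layout = ly, class = c("ss_varcomp", class(tibble::tibble())))
}
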