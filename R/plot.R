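#' Plot methods for simulation results
#'
#' `autoplot.ss_sim()` draws the estimated type I error rate against the
#' varied variance component, one line per strategy, faceted by layout,
#' with a dashed line at the nominal level. `autoplot.ss_pvq()` draws the
#' p-value Q-Q plot against the uniform distribution, one panel per
#' strategy; curves above the diagonal indicate conservative tests.
#'
#' @param object An `ss_sim` ([type1_error_study()]) or `ss_pvq`
#'   ([pvalue_quantiles()]) result.
#' @param alpha Nominal level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' grid <- dplyr::filter(simulation_grid("rcb"), a == 2, b == 4)
#' autoplot(type1_error_study(grid, reps = 2000, seed = 1))
#' @export
autoplot.ss_sim <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$variance <- ifelse(d$model == "rcb", d$sigma_B2, d$sigma_AB2)
  d$layout <- ifelse(
    d$model == "rcb",
    sprintf("%s a=%d b=%d", d$model, d$a, d$b),
    sprintf("%s a=%d b=%d c=%d", d$model, d$a, d$b, d$c))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variance, y = .data$rejection,
                                  colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~layout) +
    ggplot2::labs(x = "variance component", y = "type I error rate",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ss_sim
#' @export
autoplot.ss_pvq <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q_uniform, y = .data$p)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~strategy) +
    ggplot2::labs(x = "uniform quantile", y = "observed p-value quantile") +
    ggplot2::theme_minimal()
}
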