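#' Write a results table to disk
#'
#' Writes a test-result or simulation tibble either as machine-readable
#' TSV or as an aligned human-readable text table. F-statistics and
#' p-values are printed with 4 decimals, frequencies (rejection and
#' boundary probabilities) with 3, matching the conventions of the
#' worked-example and simulation tables.
#'
#' @param results A non-empty data frame.
#' @param path Output file path, or `""` for standard output.
#' @param format `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @examples
#' res <- anova_tests(weight_gain(), "gain", c("Sex", "Diet"))
#' tf <- tempfile(fileext = ".tsv")
#' write_report(res, tf)
#' @export
write_report <- function(results, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0L) {
    abort("empty result table; nothing to write")
  }
  d <- as.data.frame(results)
  fmt4 <- c("statistic", "p.value", "ss", "p")
  fmt3 <- c("rejection", "boundary_prob", "mc_se", "q_uniform")
  for (nm in names(d)) {
    if (nm %in% fmt4 && is.numeric(d[[nm]])) {
      d[[nm]] <- formatC(d[[nm]], format = "f", digits = 4)
    } else if (nm %in% fmt3 && is.numeric(d[[nm]])) {
      d[[nm]] <- formatC(d[[nm]], format = "f", digits = 3)
    }
  }
  if (format == "tsv") {
    utils::write.table(d, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    txt <- utils::capture.output(print(d, row.names = FALSE))
    writeLines(txt, con = if (nzchar(path)) path else stdout())
  }
  invisible(path)
}
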