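#' Adoption-curve plot for one or more runs
#'
#' Plots the number of workers exhibiting safety behavior against the
#' tick, one line per replicate, mirroring the adoption curves of the
#' scenario experiments. Requires ggplot2.
#'
#' @param results Named list: scenario name -> list of `wsb_run` (a single
#'   `wsb_run` is also accepted).
#' @return A ggplot object.
#' @export
plot_adoption <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  if (inherits(results, "wsb_run")) results <- list(run = list(results))
  df <- .timeseries_table(results)
  df$curve <- interaction(df$scenario, df$replicate)
  ggplot2::ggplot(df, ggplot2::aes(x = tick, y = exhibiting_count,
                                   group = curve, colour = scenario)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "tick", y = "workers exhibiting safety behavior",
                  colour = "scenario") +
    ggplot2::theme_minimal()
}
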