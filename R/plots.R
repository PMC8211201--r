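# Optional figure helper (ggplot2 in Suggests).

#' Boxplots of a metric across sampling regimes
#'
#' Distribution of a per-replicate metric over the number of
#' observations per individual, faceted by the number of individuals,
#' with an optional horizontal line at the reference value.
#'
#' @param results Results table from [run_experiment()].
#' @param metric Column of `results` to plot (e.g. `"density"`,
#'   `"clustering"`, `"r_com"`, `"similarity"`, `"n_communities"`).
#' @param observed Optional reference value drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_metric_by_regime <- function(results, metric = "density",
                                  observed = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_metric_by_regime requires the ggplot2 package", call. = FALSE)
  }
  if (!metric %in% names(results)) {
    stop("no column called ", metric, call. = FALSE)
  }
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = factor(.data$n_obs),
                                    y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~n_individuals, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "observations per individual", y = metric) +
    ggplot2::theme_bw()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_hline(yintercept = observed, colour = "red",
                                 linetype = 2)
  }
  p
}
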