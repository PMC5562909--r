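#' Plot time-dependent pattern populations
#'
#' Stacked view of how the conformational ensemble redistributes among
#' meta-stable patterns over time.
#'
#' @param object A `population_series` from [population_timeseries()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.population_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$population,
    colour = factor(.data$pattern)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "population",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' Plot a broadened emission spectrum
#'
#' @param object An `emission_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.emission_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy (eV)", y = "intensity (1/eV)") +
    ggplot2::theme_minimal()
}

#' Plot a prediction-validation report
#'
#' Ratio mode shows the histogram of predicted/reference with the Gaussian
#' fit overlaid; deviation mode shows the deviation histogram.
#'
#' @param object A `prediction_report`.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prediction_report <- function(object, bins = 40, ...) {
  lab <- if (object$mode == "ratio") "predicted / reference" else "predicted - reference"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::stat_function(
      fun = function(v) stats::dnorm(v, object$fit$mu, max(object$fit$sigma, 1e-12)),
      colour = "steelblue"
    ) +
    ggplot2::labs(x = lab, y = "density") +
    ggplot2::theme_minimal()
}

#' Plot the kinetic network graph
#'
#' @param graph_result Output of [build_graph()].
#' @param seed Layout seed (default 1).
#' @return Invisibly, the igraph object (plotted via base igraph plotting).
#' @export
plot_network <- function(graph_result, seed = 1L) {
  g <- graph_result$graph
  with_local_seed(seed, {
    lay <- igraph::layout_with_fr(g)
    art <- as.character(graph_result$articulation)
    igraph::V(g)$color <- ifelse(igraph::V(g)$name %in% art, "tomato", "skyblue")
    plot(g, layout = lay,
         edge.width = 1 + 4 * (igraph::E(g)$weight / max(c(igraph::E(g)$weight, 1e-12))))
  })
  invisible(g)
}
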