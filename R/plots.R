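#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot oscillator trajectories
#'
#' Activator (and optionally inhibitor) concentration against time, one
#' panel per oscillator, with the peak-count threshold marked.
#'
#' @param object An `osc_trajectory` from [simulate_oscillators()].
#' @param variable `"u"`, `"v"`, or `"both"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osc_trajectory <- function(object, variable = c("u", "both", "v"),
                                    ...) {
  variable <- match.arg(variable)
  params <- attr(object, "params")
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("u", "v"), names_to = "species",
                        values_to = "concentration")
  if (variable != "both") df <- filter(df, .data$species == variable)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                        y = .data$concentration,
                                        colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~oscillator, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (model units)", y = "concentration") +
    ggplot2::theme_minimal()
  if (!is.null(params) && variable != "v")
    p <- p + ggplot2::geom_hline(yintercept = params$peak_threshold,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' Plot a histogram baseline rule
#'
#' Bin extents coloured by the class the bin votes for.
#'
#' @param object A [fit_histogram()] rule.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.histogram_rule <- function(object, ...) {
  df <- tidy(object)
  df$label <- ifelse(df$class == 1L, "responsive", "nonresponsive")
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                   ymin = 0, ymax = 1,
                                   fill = .data$label)) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::scale_fill_manual(values = c(responsive = "#c23b3b",
                                          nonresponsive = "#3b6fc2")) +
    ggplot2::labs(x = "gene expression value", y = NULL, fill = "bin class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot an evolutionary fitness trace
#'
#' Best and mean training accuracy per generation.
#'
#' @param object An [evolve_network()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osc_evolution <- function(object, ...) {
  df <- object$trace |>
    tidyr::pivot_longer(c("best_fitness", "mean_fitness"),
                        names_to = "statistic", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "training accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a vote-threshold sweep
#'
#' @param sweep A [threshold_sweep()] tibble.
#' @return A ggplot of accuracy against the vote threshold k.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum votes for responsive (k)", y = "accuracy") +
    ggplot2::theme_minimal()
}
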