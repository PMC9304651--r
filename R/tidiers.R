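#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a count-to-class rule
#'
#' @param x A [maxima_rule()].
#' @param ... Unused.
#' @return A tibble with one row per mapped count: `count`, `class`,
#'   `label`.
#' @export
tidy.maxima_rule <- function(x, ...) {
  tibble(count = as.integer(names(x$class_of_count)),
         class = unname(x$class_of_count),
         label = ifelse(x$class_of_count == 1L, "responsive",
                        "nonresponsive"))
}

#' @rdname tidy.maxima_rule
#' @export
glance.maxima_rule <- function(x, ...) {
  tibble(output_oscillator = x$output_oscillator,
         n_counts = length(x$class_of_count),
         fallback_class = x$fallback_class,
         gene = x$gene,
         training_accuracy = attr(x, "training_accuracy") %||% NA_real_)
}

#' Tidy a histogram baseline rule
#'
#' @param x A [fit_histogram()] rule.
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin`, `lower`, `upper`, `class`.
#' @export
tidy.histogram_rule <- function(x, ...) {
  nb <- x$n_bins
  tibble(bin = seq_len(nb),
         lower = x$edges[seq_len(nb)],
         upper = x$edges[seq_len(nb) + 1L],
         class = x$class_of_bin)
}

#' @rdname tidy.histogram_rule
#' @export
glance.histogram_rule <- function(x, ...) {
  tibble(n_bins = x$n_bins, gene = x$gene,
         fallback_class = x$fallback_class,
         training_accuracy = attr(x, "training_accuracy") %||% NA_real_)
}

#' Tidy an evolutionary-search result
#'
#' @param x An [evolve_network()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-generation fitness trace; `glance()`: a
#'   one-row summary.
#' @export
tidy.osc_evolution <- function(x, ...) x$trace

#' @rdname tidy.osc_evolution
#' @export
glance.osc_evolution <- function(x, ...) {
  tibble(gene = x$gene, generations = nrow(x$trace),
         best_fitness = x$best_fitness,
         output_oscillator = x$best_rule$output_oscillator,
         seed = x$seed %||% NA_integer_)
}

#' @rdname as_tibble.network_config
#' @export
tidy.network_config <- function(x, ...) as_tibble(x)
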