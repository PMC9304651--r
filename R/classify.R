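#' Construct a count-to-class readout rule
#'
#' A `maxima_rule` translates the number of supra-threshold activator maxima
#' observed on the output oscillator into a predicted therapy outcome
#' (1 = responsive, 0 = nonresponsive). Counts never seen in training fall
#' back to `fallback_class`.
#'
#' @param responsive,nonresponsive Integer vectors of maxima counts mapped
#'   to the responsive / nonresponsive class. A count listed in both is
#'   resolved to nonresponsive with a warning (this occurs in one published
#'   rule, which is stored as printed).
#' @param output_oscillator Index of the readout oscillator.
#' @param fallback_class Class for unseen counts (default 0, matching the
#'   published rules' "any other number" clause).
#' @param gene Optional gene index the rule belongs to.
#' @return An object of class `maxima_rule`.
#' @examples
#' maxima_rule(responsive = c(1, 3, 4, 5, 9, 10),
#'             nonresponsive = c(0, 2, 6, 7, 8), output_oscillator = 3)
#' @export
maxima_rule <- function(responsive, nonresponsive, output_oscillator,
                        fallback_class = 0L, gene = NA_integer_) {
  dup <- intersect(responsive, nonresponsive)
  if (length(dup)) {
    warn(sprintf(
      "count(s) %s listed as both responsive and nonresponsive; resolved to nonresponsive",
      paste(dup, collapse = ", ")))
    responsive <- setdiff(responsive, dup)
  }
  cls <- c(setNames(rep(1L, length(responsive)), responsive),
           setNames(rep(0L, length(nonresponsive)), nonresponsive))
  cls <- cls[order(as.integer(names(cls)))]
  structure(
    list(output_oscillator = as.integer(output_oscillator),
         class_of_count = cls,
         fallback_class = as.integer(fallback_class),
         gene = as.integer(gene)),
    class = "maxima_rule"
  )
}

#' @export
print.maxima_rule <- function(x, ...) {
  cat(sprintf("<maxima_rule> output oscillator %d%s\n", x$output_oscillator,
              if (!is.na(x$gene)) sprintf(" (gene %d)", x$gene) else ""))
  cat("  responsive counts:   ",
      paste(names(x$class_of_count)[x$class_of_count == 1L], collapse = ", "),
      "\n")
  cat("  nonresponsive counts:",
      paste(names(x$class_of_count)[x$class_of_count == 0L], collapse = ", "),
      "\n")
  cat(sprintf("  fallback class: %d\n", x$fallback_class))
  invisible(x)
}

# Majority class per count value; ties go to nonresponsive (0).
majority_map <- function(counts, labels) {
  tab <- table(count = counts, label = labels)
  n1 <- if ("1" %in% colnames(tab)) tab[, "1"] else rep(0, nrow(tab))
  n0 <- if ("0" %in% colnames(tab)) tab[, "0"] else rep(0, nrow(tab))
  setNames(as.integer(n1 > n0), rownames(tab))
}

#' Induce the optimal count-to-class rule from training counts
#'
#' For every oscillator, each observed maxima count is mapped to the
#' majority outcome among training records showing that count (per-count
#' majority is the training-error-optimal count-to-class map). The output
#' oscillator is the one whose induced map misclassifies the fewest training
#' records; ties go to the lowest index, tied counts to nonresponsive, and
#' unseen counts to the global training majority.
#'
#' @param counts Integer matrix of maxima counts (rows = records, columns =
#'   oscillators), as returned by [simulate_network()], or a data frame
#'   containing `osc_*` columns such as [simulate_table()] output.
#' @param labels Binary outcome per record (0 = nonresponsive,
#'   1 = responsive).
#' @param gene Optional gene index stored on the rule.
#' @return A `maxima_rule` with attribute `"training_accuracy"`.
#' @examples
#' counts <- cbind(osc_1 = c(1, 1, 2, 2), osc_2 = c(0, 1, 0, 1))
#' induce_rule(counts, labels = c(0, 0, 1, 1))
#' @export
induce_rule <- function(counts, labels, gene = NA_integer_) {
  counts <- counts_matrix(counts)
  labels <- as.integer(labels)
  stopifnot(nrow(counts) == length(labels), nrow(counts) >= 1L,
            all(labels %in% 0:1))
  errs <- integer(ncol(counts))
  maps <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    maps[[j]] <- majority_map(counts[, j], labels)
    pred <- unname(maps[[j]][as.character(counts[, j])])
    errs[j] <- sum(pred != labels)
  }
  best <- which.min(errs)  # lowest index wins ties
  n1 <- sum(labels == 1L)
  fallback <- as.integer(n1 > length(labels) - n1)
  map <- maps[[best]]
  rule <- maxima_rule(
    responsive = as.integer(names(map)[map == 1L]),
    nonresponsive = as.integer(names(map)[map == 0L]),
    output_oscillator = best, fallback_class = fallback, gene = gene
  )
  attr(rule, "training_accuracy") <- 1 - errs[best] / length(labels)
  rule
}

counts_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    osc <- grep("^osc_", names(counts), value = TRUE)
    if (!length(osc)) abort("`counts` data frame must contain osc_* columns")
    counts <- as.matrix(counts[osc])
  }
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  storage.mode(counts) <- "integer"
  counts
}

#' Predict outcomes from maxima counts
#'
#' @param object A [maxima_rule()].
#' @param counts Count matrix (the rule's output-oscillator column is used)
#'   or an integer vector of output-oscillator counts.
#' @param ... Unused.
#' @return Integer vector of predicted classes.
#' @export
predict.maxima_rule <- function(object, counts, ...) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    cm <- counts_matrix(counts)
    counts <- cm[, object$output_oscillator]
  }
  pred <- object$class_of_count[as.character(counts)]
  pred[is.na(pred)] <- object$fallback_class
  unname(pred)
}

#' Evaluate a classification rule
#'
#' Computes accuracy and the four outcome-stratified confusion cells:
#' correctly / wrongly determined nonresponsive cases are true-nonresponsive
#' records predicted 0 / 1, and likewise for responsive.
#'
#' @param rule A [maxima_rule()] or [histogram_rule][fit_histogram] object.
#' @param x Maxima counts (for a `maxima_rule`) or raw expression values
#'   (for a `histogram_rule`).
#' @param labels True binary outcomes.
#' @return One-row tibble with columns `accuracy`, `correct_nonresponsive`,
#'   `correct_responsive`, `wrong_nonresponsive`, `wrong_responsive`, `n`.
#' @examples
#' r <- maxima_rule(responsive = 1, nonresponsive = 0, output_oscillator = 1)
#' evaluate_rule(r, c(0, 1, 1, 0), labels = c(0, 1, 0, 0))
#' @export
evaluate_rule <- function(rule, x, labels) {
  pred <- predict(rule, x)
  labels <- as.integer(labels)
  stopifnot(length(pred) == length(labels))
  tibble(
    accuracy = mean(pred == labels),
    correct_nonresponsive = sum(labels == 0L & pred == 0L),
    correct_responsive = sum(labels == 1L & pred == 1L),
    wrong_nonresponsive = sum(labels == 0L & pred == 1L),
    wrong_responsive = sum(labels == 1L & pred == 0L),
    n = length(labels)
  )
}

#' Equal-width-histogram baseline classifier
#'
#' Divides the observed range of one gene's raw expression values into
#' `n_bins` bins of equal width and assigns each bin the majority outcome of
#' the training records falling in it. Bins are half-open `[lo, hi)` with the
#' last bin closed; at prediction time, values outside the training range are
#' clamped into the nearest edge bin. This is the no-dynamics baseline the
#' oscillator networks are compared against.
#'
#' @param values Raw expression values of one gene.
#' @param labels Binary outcomes.
#' @param n_bins Number of bins (default 10).
#' @param gene Optional gene index stored on the rule.
#' @return An object of class `histogram_rule` with fields `edges`
#'   (`n_bins + 1` boundaries), `class_of_bin`, and `fallback_class` (global
#'   majority, used for empty bins), plus attribute `"training_accuracy"`.
#' @examples
#' fit_histogram(c(1, 2, 3, 10, 11, 12), labels = c(0, 0, 0, 1, 1, 1))
#' @export
fit_histogram <- function(values, labels, n_bins = 10, gene = NA_integer_) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), all(labels %in% 0:1))
  if (max(values) <= min(values))
    abort("degenerate expression values: max must exceed min")
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n1 <- sum(labels == 1L)
  fallback <- as.integer(n1 > length(labels) - n1)
  cls <- rep(NA_integer_, n_bins)
  mm <- majority_map(bin, labels)
  cls[as.integer(names(mm))] <- mm
  cls[is.na(cls)] <- fallback
  rule <- structure(
    list(edges = edges, class_of_bin = cls, fallback_class = fallback,
         gene = as.integer(gene), n_bins = n_bins),
    class = "histogram_rule"
  )
  attr(rule, "training_accuracy") <- mean(predict(rule, values) == labels)
  rule
}

#' @export
print.histogram_rule <- function(x, ...) {
  cat(sprintf("<histogram_rule> %d equal-width bins over [%g, %g]%s\n",
              x$n_bins, min(x$edges), max(x$edges),
              if (!is.na(x$gene)) sprintf(" (gene %d)", x$gene) else ""))
  cat("  responsive bins:", paste(which(x$class_of_bin == 1L), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname fit_histogram
#' @param object A `histogram_rule`.
#' @param values Raw expression values to classify.
#' @param ... Unused.
#' @export
predict.histogram_rule <- function(object, values, ...) {
  bin <- findInterval(values, object$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  unname(object$class_of_bin[bin])
}

#' Accuracy of the two constant classifiers
#'
#' The trivial baselines: always predict responsive ("always treat") or
#' always predict nonresponsive.
#'
#' @param labels Binary outcome vector.
#' @return A tibble with columns `rule` and `accuracy`.
#' @examples
#' constant_baseline(c(rep(0, 126), rep(1, 113)))
#' @export
constant_baseline <- function(labels) {
  labels <- as.integer(labels)
  tibble(
    rule = c("always_responsive", "always_nonresponsive"),
    accuracy = c(mean(labels == 1L), mean(labels == 0L))
  )
}

# --- published readout rules ------------------------------------------------

#' Write or read a readout rule as JSON
#'
#' Rules are stored as lists of responsive and nonresponsive counts (the
#' published-table layout). A count listed on both sides is kept as printed
#' in the file and resolved to nonresponsive on load, with a warning.
#'
#' @param rule A [maxima_rule()].
#' @param path JSON file path.
#' @return `write_rule_json()` returns `path` invisibly; `read_rule_json()`
#'   a `maxima_rule`.
#' @export
write_rule_json <- function(rule, path) {
  obj <- list(
    gene = rule$gene,
    output_oscillator = rule$output_oscillator,
    responsive = as.integer(names(rule$class_of_count)[rule$class_of_count == 1L]),
    nonresponsive = as.integer(names(rule$class_of_count)[rule$class_of_count == 0L]),
    fallback = rule$fallback_class
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_json
#' @export
read_rule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  maxima_rule(
    responsive = as.integer(unlist(obj$responsive)),
    nonresponsive = as.integer(unlist(obj$nonresponsive)),
    output_oscillator = obj$output_oscillator,
    fallback_class = obj$fallback %||% 0L,
    gene = obj$gene %||% NA_integer_
  )
}

#' @rdname published_networks
#' @export
published_rules <- function(genes = 1:15) {
  dir <- system.file("extdata", "rules", "table4", package = "concilium")
  out <- lapply(genes, function(g) {
    read_rule_json(file.path(dir, sprintf("gene_%02d.json", g)))
  })
  setNames(out, sprintf("gene_%02d", genes))
}
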