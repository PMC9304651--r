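#' Assemble a concilium of single-gene networks
#'
#' A concilium is a majority-voting ensemble: each member is a trained
#' network plus its count-to-class readout rule, specialized for one gene,
#' and casts one vote per record. The verdict is responsive when at least
#' `k` members vote responsive.
#'
#' @param networks List of [network_config()] objects with distinct
#'   `input_gene`s.
#' @param rules List of [maxima_rule()] objects, parallel to `networks`.
#' @return An object of class `concilium`.
#' @examples
#' \donttest{
#' conc <- published_concilium()
#' }
#' @export
concilium <- function(networks, rules) {
  stopifnot(length(networks) == length(rules), length(networks) >= 1)
  genes <- map_int(networks, "input_gene")
  if (anyDuplicated(genes))
    abort("concilium members must read distinct genes")
  members <- purrr::map2(networks, rules,
                         function(n, r) list(network = n, rule = r))
  structure(list(members = members, genes = genes), class = "concilium")
}

#' The published 15-member concilium
#'
#' @return A [concilium()] built from the bundled trained networks and
#'   rules. The gene-12 rule carries a printed count conflict that is
#'   resolved to nonresponsive on load (with a warning, suppressed here).
#' @export
published_concilium <- function() {
  nets <- published_networks()
  rules <- suppressWarnings(published_rules())
  concilium(nets, rules)
}

#' @export
print.concilium <- function(x, ...) {
  cat(sprintf("<concilium> %d member network(s), genes: %s\n",
              length(x$members), paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Collect member votes for every record
#'
#' Each member normalizes its own gene's expression value, simulates its
#' network, and classifies via its readout rule.
#'
#' @param object A [concilium()].
#' @param data Patient tibble.
#' @param params [oscillator_params()] for all simulations.
#' @param stats Normalization ranges (default [gene_ranges]).
#' @return Tibble with one row per record: `record`, `votes_for` (members
#'   voting responsive), plus `outcome` and `drug` when present in `data`.
#' @export
concilium_votes <- function(object, data, params = oscillator_params(),
                            stats = concilium::gene_ranges) {
  stopifnot(inherits(object, "concilium"))
  votes <- map(object$members, function(mem) {
    cfg <- mem$network
    e <- gene_column(data, cfg$input_gene)
    if (anyNA(e))
      abort(sprintf("missing expression value for gene %d", cfg$input_gene))
    p <- normalize_expression(e, cfg$input_gene, stats)
    counts <- simulate_network(cfg, p, params)
    predict(mem$rule, counts)
  })
  out <- tibble(record = seq_len(nrow(data)),
                votes_for = Reduce(`+`, votes))
  if ("outcome" %in% names(data)) out$outcome <- as.integer(data$outcome)
  if ("drug" %in% names(data)) out$drug <- data$drug
  out
}

#' Majority-voting verdict at a threshold
#'
#' @inheritParams concilium_votes
#' @param k Minimum number of responsive votes required to declare a record
#'   responsive (k = 8 is strict majority for 15 members).
#' @return The votes tibble of [concilium_votes()] with an added `decision`
#'   column (1 = responsive).
#' @examples
#' \donttest{
#' conc <- published_concilium()
#' tab <- synthesize_patients(5, seed = 1)
#' predict(conc, tab, k = 8)
#' }
#' @export
predict.concilium <- function(object, data, k = 8,
                              params = oscillator_params(),
                              stats = concilium::gene_ranges, ...) {
  stopifnot(k >= 1)
  votes <- concilium_votes(object, data, params, stats)
  votes$decision <- as.integer(votes$votes_for >= k)
  votes
}

#' Sweep the vote threshold
#'
#' Evaluates the concilium verdict "responsive iff at least `k` votes for"
#' over a range of thresholds, optionally restricted to one drug's records.
#'
#' @inheritParams concilium_votes
#' @param k_values Thresholds to evaluate (default 8:14).
#' @param drug Optional drug filter (`"PS341"` or `"DEX"`).
#' @param votes Optional precomputed [concilium_votes()] table, to avoid
#'   re-simulating when sweeping several filters.
#' @return Tibble with one row per `k`: accuracy and the four
#'   outcome-stratified confusion cells.
#' @export
threshold_sweep <- function(object, data, k_values = 8:14, drug = NULL,
                            params = oscillator_params(),
                            stats = concilium::gene_ranges, votes = NULL) {
  stopifnot(length(k_values) >= 1)
  if (is.null(votes)) votes <- concilium_votes(object, data, params, stats)
  if (!is.null(drug)) votes <- filter(votes, .data$drug == !!drug)
  if (!"outcome" %in% names(votes))
    abort("`data` must contain an `outcome` column to evaluate accuracy")
  list_rbind(map(as.integer(k_values), function(k) {
    pred <- as.integer(votes$votes_for >= k)
    truth <- votes$outcome
    tibble(k = k,
           accuracy = mean(pred == truth),
           correct_nonresponsive = sum(truth == 0L & pred == 0L),
           correct_responsive = sum(truth == 1L & pred == 1L),
           wrong_nonresponsive = sum(truth == 0L & pred == 1L),
           wrong_responsive = sum(truth == 1L & pred == 0L),
           n = length(truth))
  }))
}

#' Perturb one network parameter by a relative amount
#'
#' Scales a single named parameter by `1 + direction * magnitude` (the
#' robustness analysis uses +/- 1%), leaving everything else identical.
#' After perturbation the readout rule should be re-induced on the training
#' table, since the best output oscillator can change.
#'
#' @param net A [network_config()].
#' @param parameter One of `"t_max"`, `"t_start"`, `"t_end"`, `"alpha"`,
#'   `"beta"`, or `"t_illum_<j>"` with `<j>` the index of a normal
#'   oscillator.
#' @param direction +1 or -1.
#' @param magnitude Relative change (default 0.01).
#' @return The perturbed `network_config`.
#' @examples
#' cfg <- published_networks(1)[[1]]
#' perturb_network(cfg, "t_max", +1)$t_max / cfg$t_max
#' @export
perturb_network <- function(net, parameter, direction = 1,
                            magnitude = 0.01) {
  stopifnot(inherits(net, "network_config"), direction %in% c(-1, 1))
  fac <- 1 + direction * magnitude
  if (parameter %in% c("t_max", "t_start", "t_end", "alpha", "beta")) {
    net[[parameter]] <- net[[parameter]] * fac
  } else if (grepl("^t_illum_[0-9]+$", parameter)) {
    j <- as.integer(sub("t_illum_", "", parameter))
    normals <- which(net$roles == "normal")
    pos <- match(j, normals)
    if (is.na(pos))
      abort(sprintf("oscillator %d is not a normal oscillator", j))
    net$t_illum_normal[pos] <- net$t_illum_normal[pos] * fac
  } else {
    abort(sprintf("unknown parameter `%s`", parameter))
  }
  net$output_oscillator <- NA_integer_  # rule must be re-induced
  net
}
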