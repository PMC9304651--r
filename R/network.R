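#' Define a classifier network of coupled oscillators
#'
#' A network is a small set of coupled Oregonator oscillators, each either an
#' *input* oscillator (its illumination switch time encodes the normalized
#' gene-expression value through the affine map of [t_illum_for_input()]) or
#' a *normal* one (fixed switch time). The three-oscillator family used for
#' training fixes oscillator 1 as input and oscillator 3 as normal; the role
#' of oscillator 2 is free.
#'
#' @param roles Character vector of `"input"` / `"normal"`, one per
#'   oscillator. At least one of each is required.
#' @param input_gene Gene index (1..15) whose normalized expression value
#'   feeds every input oscillator.
#' @param t_max Observation horizon in model time units.
#' @param t_start,t_end Endpoints of the input map: a normalized value `p`
#'   yields switch time `t_start + (t_end - t_start) * p`. `t_start > t_end`
#'   (a decreasing map) is legal.
#' @param alpha Lumped activator decay rate (>= 0).
#' @param beta Lumped activator exchange rate (>= 0).
#' @param t_illum_normal Named or positional numeric vector of switch times
#'   for the normal oscillators, in oscillator order.
#' @param coupling Symmetric 0/1 coupling matrix; default all-to-all.
#' @param output_oscillator Index of the readout oscillator, usually set
#'   after training; `NA` if not yet chosen.
#' @return An object of class `network_config`.
#' @examples
#' network_config(roles = c("input", "normal", "normal"), input_gene = 13,
#'                t_max = 80, t_start = 2.48, t_end = 51.09,
#'                alpha = 0.7, beta = 0.07, t_illum_normal = c(5, 2))
#' @export
network_config <- function(roles, input_gene, t_max, t_start, t_end,
                           alpha, beta, t_illum_normal = numeric(),
                           coupling = NULL, output_oscillator = NA_integer_) {
  m <- length(roles)
  if (!all(roles %in% c("input", "normal")))
    abort("`roles` must contain only \"input\" and \"normal\"")
  if (!any(roles == "input") || !any(roles == "normal"))
    abort("a network needs at least one input and one normal oscillator")
  n_normal <- sum(roles == "normal")
  if (length(t_illum_normal) != n_normal)
    abort(sprintf("`t_illum_normal` must have %d value(s), one per normal oscillator",
                  n_normal))
  stopifnot(t_max > 0, alpha >= 0, beta >= 0)
  S <- check_coupling(coupling, m)
  cfg <- structure(
    list(m = m, roles = roles, input_gene = as.integer(input_gene),
         t_max = t_max, t_start = t_start, t_end = t_end,
         alpha = alpha, beta = beta,
         t_illum_normal = unname(as.numeric(t_illum_normal)),
         coupling = S,
         output_oscillator = as.integer(output_oscillator)),
    class = "network_config"
  )
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> m = %d, gene %d\n", x$m, x$input_gene))
  cat(sprintf("  roles: %s\n", paste(x$roles, collapse = ", ")))
  cat(sprintf("  t_max = %g, input map %g -> %g, alpha = %g, beta = %g\n",
              x$t_max, x$t_start, x$t_end, x$alpha, x$beta))
  if (length(x$t_illum_normal))
    cat(sprintf("  t_illum (normal): %s\n",
                paste(signif(x$t_illum_normal, 5), collapse = ", ")))
  if (!is.na(x$output_oscillator))
    cat(sprintf("  output oscillator: %d\n", x$output_oscillator))
  invisible(x)
}

#' One-row tibble view of a network configuration
#'
#' @param x A `network_config`.
#' @param ... Unused.
#' @return A one-row tibble of the scalar parameters, with the normal-oscillator
#'   switch times in list-column `t_illum_normal`.
#' @export
as_tibble.network_config <- function(x, ...) {
  tibble(gene = x$input_gene, m = x$m,
         roles = paste(x$roles, collapse = ","),
         t_max = x$t_max, t_start = x$t_start, t_end = x$t_end,
         alpha = x$alpha, beta = x$beta,
         t_illum_normal = list(x$t_illum_normal),
         output_oscillator = x$output_oscillator)
}

#' Map a normalized expression value to an illumination switch time
#'
#' The affine encoding `t_illum = t_start + (t_end - t_start) * p`. Values of
#' `p` outside `[0, 1]` (expression outside the training range) are accepted
#' and extrapolate linearly.
#'
#' @param p Normalized expression value(s).
#' @param t_start,t_end Map endpoints in model time units; `t_start > t_end`
#'   gives a decreasing map.
#' @return Switch time(s) in model time units.
#' @examples
#' t_illum_for_input(0.5, t_start = 2.48, t_end = 51.09)
#' @export
t_illum_for_input <- function(p, t_start, t_end) {
  t_start + (t_end - t_start) * p
}

#' Per-oscillator illumination schedule for one record
#'
#' @param config A [network_config()].
#' @param p A single normalized expression value.
#' @return Numeric vector of switch times, one per oscillator: input
#'   oscillators via the affine map (all sharing the same value), normal
#'   oscillators from the configured fixed times.
#' @export
schedule_for <- function(config, p) {
  stopifnot(inherits(config, "network_config"), length(p) == 1L)
  till <- numeric(config$m)
  till[config$roles == "input"] <-
    t_illum_for_input(p, config$t_start, config$t_end)
  till[config$roles == "normal"] <- config$t_illum_normal
  till
}

#' Simulate a network for one record
#'
#' Builds the illumination schedule for a normalized value `p`, integrates
#' the coupled network over `[0, t_max]` from the suppressed steady state,
#' and counts the supra-threshold activator maxima on every oscillator.
#'
#' @inheritParams schedule_for
#' @param params An [oscillator_params()] object.
#' @return Integer vector of maxima counts, one per oscillator.
#' @examples
#' cfg <- network_config(roles = c("input", "normal"), input_gene = 1,
#'                       t_max = 20, t_start = 1, t_end = 15,
#'                       alpha = 0.7, beta = 0.07, t_illum_normal = 3)
#' simulate_record(cfg, p = 0.5)
#' @export
simulate_record <- function(config, p, params = oscillator_params()) {
  drop(simulate_network(config, p, params))
}

#' Simulate a network across many records
#'
#' Vectorized form of [simulate_record()]: one integration per distinct
#' normalized value, all performed in compiled code.
#'
#' @inheritParams simulate_record
#' @param p Vector of normalized expression values.
#' @return Integer matrix with one row per value of `p` and one column per
#'   oscillator, containing supra-threshold maxima counts.
#' @export
simulate_network <- function(config, p, params = oscillator_params()) {
  stopifnot(inherits(config, "network_config"))
  till <- t(vapply(p, function(pi) schedule_for(config, pi),
                   numeric(config$m)))
  if (config$m == 1L) till <- matrix(till, ncol = 1L)
  counts <- withCallingHandlers(
    cpp_counts_batch(till, params$epsilon, params$q, params$f,
                     config$alpha, config$beta, config$coupling,
                     config$t_max, params$dt, 10L, params$peak_threshold),
    error = function(e) e
  )
  if (inherits(counts, "error"))
    abort(c("network integration failed",
            sprintf("gene %d, t_max = %g, alpha = %g, beta = %g",
                    config$input_gene, config$t_max, config$alpha,
                    config$beta)),
          parent = counts)
  colnames(counts) <- paste0("osc_", seq_len(config$m))
  counts
}

#' Maxima counts for every record of a patient table
#'
#' Normalizes the configured gene's expression column and simulates the
#' network for each record, returning a tidy per-record count table.
#'
#' @inheritParams simulate_record
#' @param data A patient tibble with `gene_01`..`gene_15` columns (see
#'   [read_patient_table()]), and optionally `outcome`.
#' @param stats Per-gene normalization ranges; defaults to the published
#'   training ranges [gene_ranges].
#' @return A tibble with columns `p`, `osc_1`..`osc_m`, plus `outcome` when
#'   present in `data`.
#' @export
simulate_table <- function(config, data, params = oscillator_params(),
                           stats = concilium::gene_ranges) {
  p <- normalize_expression(gene_column(data, config$input_gene),
                            config$input_gene, stats)
  counts <- simulate_network(config, p, params)
  out <- bind_cols(tibble(p = p), as_tibble(counts))
  if ("outcome" %in% names(data)) out$outcome <- data$outcome
  out
}

# --- JSON serialization (flat object mirroring the published-table columns) --

#' Write or read a network configuration as JSON
#'
#' The on-disk format is a flat JSON object with the published parameter
#' names (`t_max`, `t_start`, `t_end`, `alpha`, `beta`, `input_oscillators`,
#' `normal_oscillators`, `t_illum`, `output_oscillator`, `gene`), so the 15
#' published three-oscillator networks ship as one fixture file per gene.
#'
#' @param config A [network_config()].
#' @param path JSON file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `network_config`.
#' @export
write_network_json <- function(config, path) {
  obj <- list(
    gene = config$input_gene,
    m = config$m,
    t_max = config$t_max, t_start = config$t_start, t_end = config$t_end,
    alpha = config$alpha, beta = config$beta,
    input_oscillators = which(config$roles == "input"),
    normal_oscillators = which(config$roles == "normal"),
    t_illum = as.list(setNames(config$t_illum_normal,
                               which(config$roles == "normal"))),
    output_oscillator = config$output_oscillator
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- rep("normal", obj$m)
  roles[unlist(obj$input_oscillators)] <- "input"
  network_config(
    roles = roles, input_gene = obj$gene,
    t_max = obj$t_max, t_start = obj$t_start, t_end = obj$t_end,
    alpha = obj$alpha, beta = obj$beta,
    t_illum_normal = unlist(obj$t_illum),
    output_oscillator = obj$output_oscillator %||% NA_integer_
  )
}

#' Published single-gene networks and readout rules
#'
#' Loads the 15 trained three-oscillator network configurations (and their
#' count-to-class readout rules) bundled with the package, one per gene of
#' [gene_ranges].
#'
#' @param genes Gene indices to load (default all 15).
#' @return `published_networks()`: a named list of `network_config` objects;
#'   `published_rules()`: a named list of `maxima_rule` objects.
#' @examples
#' nets <- published_networks(13)
#' nets[["gene_13"]]
#' @export
published_networks <- function(genes = 1:15) {
  dir <- system.file("extdata", "networks", "table3", package = "concilium")
  out <- lapply(genes, function(g) {
    read_network_json(file.path(dir, sprintf("gene_%02d.json", g)))
  })
  setNames(out, sprintf("gene_%02d", genes))
}
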