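#' Generate a synthetic patient table
#'
#' Draws records that emulate the structure of the clinical training set:
#' per-gene expression values confined to the published ranges and a weak,
#' heavily overlapping class-conditional signal. For each gene, values are
#' drawn from class-conditional truncated normal distributions inside the
#' gene's `[min, max]` range; the two class means sit at fractions
#' `0.5 -/+ 0.3 * (1 - overlap)` of the range (standard deviation 0.15 of
#' the range), so `overlap = 1` gives identically distributed classes and
#' `overlap = 0` gives nearly separable ones. The default class balance is
#' the clinical 126 nonresponsive / 113 responsive, scaled to `n`, with drug
#' labels assigned in the clinical 169:70 PS341:DEX proportion.
#'
#' The generator validates machinery (rule induction, evolutionary search,
#' voting) on data with known structure; it does not reproduce the clinical
#' accuracy figures.
#'
#' @param n Number of records (>= 2).
#' @param stats Per-gene ranges, defaulting to the published [gene_ranges].
#' @param class_balance Two counts, nonresponsive then responsive, scaled to
#'   `n` (default the clinical 126/113).
#' @param overlap Class-separation control in `[0, 1]`: 1 = no signal,
#'   0 = strong signal.
#' @param seed Optional RNG seed for a reproducible table.
#' @return A patient tibble with columns `gene_01`..`gene_15`, `outcome`,
#'   `drug`, `patient_id`.
#' @examples
#' synthesize_patients(20, overlap = 0.5, seed = 1)
#' @export
synthesize_patients <- function(n = 239, stats = concilium::gene_ranges,
                                class_balance = c(nonresponsive = 126,
                                                  responsive = 113),
                                overlap = 0.8, seed = NULL) {
  stopifnot(n >= 2, overlap >= 0, overlap <= 1, length(class_balance) == 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n0 <- max(1L, round(n * class_balance[[1]] / sum(class_balance)))
  n0 <- min(n0, n - 1L)
  outcome <- sample(c(rep(0L, n0), rep(1L, n - n0)))
  sep <- 1 - overlap
  out <- tibble(.rows = n)
  for (i in seq_len(nrow(stats))) {
    lo <- stats$min[i]; hi <- stats$max[i]; rng <- hi - lo
    mu <- lo + rng * (0.5 + 0.3 * sep * (2 * outcome - 1))
    out[[sprintf("gene_%02d", stats$gene[i])]] <-
      rtruncnorm(n, mean = mu, sd = 0.15 * rng, lower = lo, upper = hi)
  }
  out$outcome <- outcome
  out$drug <- sample(c("PS341", "DEX"), n, replace = TRUE,
                     prob = c(169, 70) / 239)
  out$patient_id <- sprintf("SYN%04d", seq_len(n))
  out
}

# Truncated-normal draws by inverse-CDF; `mean`, `sd` may be vectors.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  a <- pnorm(lower, mean, sd)
  b <- pnorm(upper, mean, sd)
  qnorm(a + runif(n) * (b - a), mean, sd)
}
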