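# Shared fixtures for the suite. Everything is generated in code.

# A tiny, perfectly separable two-gene-relevant patient table: gene_01
# carries the class signal, all other genes are mid-range noise.
toy_patient_table <- function(n = 6) {
  ranges <- concilium::gene_ranges
  out <- tibble::tibble(.rows = n)
  outcome <- rep_len(c(0L, 1L), n)
  for (i in seq_len(nrow(ranges))) {
    lo <- ranges$min[i]
    hi <- ranges$max[i]
    val <- if (i == 1) lo + (hi - lo) * ifelse(outcome == 1, 0.9, 0.1)
           else rep((lo + hi) / 2, n)
    val <- round(val, 3)  # compact decimal form survives CSV round-trips
    out[[sprintf("gene_%02d", i)]] <- val
  }
  out$outcome <- outcome
  out$drug <- rep_len(c("PS341", "DEX"), n)
  out$patient_id <- sprintf("TOY%02d", seq_len(n))
  out
}

# Coarse-step integration settings for network-level checks: 5th-order
# Cash-Karp at dt = 0.01 gives counts identical to the dt = 1e-3 reference
# on these problems (asserted in test-dynamics.R).
coarse_params <- function() oscillator_params(dt = 0.01)

# Exhaustive best count-to-class map: enumerates all 2^k assignments of the
# k distinct counts of each oscillator and returns the best achievable
# training accuracy. Independent of the induction code path.
brute_force_best_accuracy <- function(counts, labels) {
  best <- 0
  for (j in seq_len(ncol(counts))) {
    vals <- sort(unique(counts[, j]))
    k <- length(vals)
    for (mask in 0:(2^k - 1)) {
      cls <- as.integer(intToBits(mask)[seq_len(k)])
      pred <- cls[match(counts[, j], vals)]
      best <- max(best, mean(pred == labels))
    }
  }
  best
}

# The scaled-down evolutionary run shared by several acceptance checks:
# 50 generations, 200 synthetic records at overlap 0.3, fixed seeds.
# Cached so the suite pays for it once.
acceptance_ga_run <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      tab <- synthesize_patients(200, overlap = 0.3, seed = 101)
      ga <- ga_config(generations = 50, seed = 1,
                      bounds = list(t_max = c(10, 20), alpha = c(0, 1),
                                    beta = c(0, 0.2)))
      cached <<- evolve_network(tab, gene = 1, ga = ga,
                                params = coarse_params())
    }
    cached
  }
})

# Documented drop-in location for the clinical training table (not shipped:
# it is third-party patient data). Returns NA when absent.
clinical_table_file <- function() {
  candidates <- c(
    system.file("extdata", "clinical", "clinical_table.csv",
                package = "concilium"),
    system.file("extdata", "clinical", "clinical_table.xlsx",
                package = "concilium"),
    file.path("..", "..", "inst", "extdata", "clinical",
              "clinical_table.csv")
  )
  candidates <- candidates[nzchar(candidates) & file.exists(candidates)]
  if (length(candidates)) candidates[[1]] else NA_character_
}
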