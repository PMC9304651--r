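#' Published single-parameter robustness perturbations
#'
#' The robustness analysis modifies one randomly chosen parameter of each
#' trained network by +/- 1% and re-induces the readout rule. This table
#' records which parameter moved in which direction for each gene's
#' network; apply it with [perturb_network()].
#'
#' @format A tibble with columns `gene`, `parameter`, `direction`.
#' @export
published_perturbations <- tibble::tribble(
  ~gene, ~parameter,  ~direction,
  1L,  "t_max",     +1,
  2L,  "beta",      +1,
  3L,  "beta",      -1,
  4L,  "t_start",   +1,
  5L,  "t_illum_3", -1,
  6L,  "t_end",     +1,
  7L,  "beta",      +1,
  8L,  "t_illum_2", -1,
  9L,  "alpha",     -1,
  10L, "t_illum_3", +1,
  11L, "t_illum_2", +1,
  12L, "t_end",     +1,
  13L, "beta",      -1,
  14L, "t_max",     +1,
  15L, "t_illum_3", -1
)
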