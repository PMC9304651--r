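test_that("input mapping is the affine encoding, extrapolating out of range", {
  expect_equal(t_illum_for_input(0, 10, 50), 10)
  expect_equal(t_illum_for_input(1, 10, 50), 50)
  # the published RPS7 network maps p = 0.5 to the midpoint
  expect_equal(t_illum_for_input(0.5, 2.48, 51.09), 26.785)
  # decreasing maps and out-of-range inputs are legal
  expect_equal(t_illum_for_input(0.5, 50, 10), 30)
  expect_equal(t_illum_for_input(-0.25, 0, 40), -10)
})

test_that("network configuration validates its invariants", {
  expect_error(network_config(roles = c("input", "input"), input_gene = 1,
                              t_max = 20, t_start = 1, t_end = 10,
                              alpha = 0.5, beta = 0.05),
               "at least one input and one normal")
  expect_error(network_config(roles = c("normal", "normal"), input_gene = 1,
                              t_max = 20, t_start = 1, t_end = 10,
                              alpha = 0.5, beta = 0.05,
                              t_illum_normal = c(1, 2)),
               "at least one input and one normal")
  expect_error(network_config(roles = c("input", "normal"), input_gene = 1,
                              t_max = 20, t_start = 1, t_end = 10,
                              alpha = 0.5, beta = 0.05,
                              t_illum_normal = c(1, 2)),
               "one per normal oscillator")
  bad <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  expect_error(network_config(roles = c("input", "normal"), input_gene = 1,
                              t_max = 20, t_start = 1, t_end = 10,
                              alpha = 0.5, beta = 0.05, t_illum_normal = 3,
                              coupling = bad),
               "symmetric")
})

test_that("schedules assign the shared input time and the fixed normal times", {
  cfg <- network_config(roles = c("input", "input", "normal"),
                        input_gene = 13, t_max = 80, t_start = 2.48,
                        t_end = 51.09, alpha = 0.7, beta = 0.07,
                        t_illum_normal = 2.0)
  s <- schedule_for(cfg, 0.5)
  expect_equal(s, c(26.785, 26.785, 2.0))
})

test_that("record simulation inherits the dynamics' exact limits", {
  p <- coarse_params()
  # all-normal-but-one symmetric configuration: equal counts everywhere
  cfg <- network_config(roles = c("input", "normal", "normal"),
                        input_gene = 1, t_max = 25, t_start = 4, t_end = 4,
                        alpha = 0.3, beta = 0.05, t_illum_normal = c(4, 4))
  cts <- simulate_record(cfg, p = 0.7, params = p)
  expect_true(all(cts == cts[1]))
  # beta = 0 decouples: each count equals the isolated-oscillator count
  cfg2 <- network_config(roles = c("input", "normal"), input_gene = 1,
                         t_max = 30, t_start = 2, t_end = 12, alpha = 0,
                         beta = 0, t_illum_normal = 6)
  cts2 <- simulate_record(cfg2, p = 0.5, params = p)
  iso <- function(till) {
    attr(simulate_oscillators(till, 30, params = p), "counts")
  }
  expect_identical(cts2[["osc_1"]], iso(7))
  expect_identical(cts2[["osc_2"]], iso(6))
})

test_that("counts are bounded, deterministic and piecewise constant in p", {
  cfg <- published_networks(13)[[1]]
  p <- seq(0, 1, 0.1)
  cts <- simulate_network(cfg, p, coarse_params())
  # bounded by the free-running period over the horizon
  expect_true(all(cts >= 0))
  expect_true(all(cts <= ceiling(cfg$t_max / 8.2) + 1))
  # the published readout range for this network is 0..10
  expect_true(all(cts[, cfg$output_oscillator] %in% 0:10))
  # deterministic across runs
  expect_identical(cts, simulate_network(cfg, p, coarse_params()))
  # counts form a step function of p: a 1e-6 nudge moves them by at most 1
  for (pp in c(0.25, 0.6)) {
    a <- simulate_record(cfg, pp, coarse_params())
    b <- simulate_record(cfg, pp + 1e-6, coarse_params())
    expect_true(all(abs(a - b) <= 1L))
  }
})

test_that("configurations round-trip through the JSON layout", {
  cfg <- network_config(roles = c("input", "normal", "normal"),
                        input_gene = 7, t_max = 44.4, t_start = 1.25,
                        t_end = 40, alpha = 0.63, beta = 0.06,
                        t_illum_normal = c(3.51, 5.28),
                        output_oscillator = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(cfg, path)
  back <- read_network_json(path)
  expect_equal(back[names(back) != "coupling"],
               cfg[names(cfg) != "coupling"])
  expect_identical(back$coupling, cfg$coupling)
})

test_that("the 15 published networks load with the printed parameters", {
  nets <- published_networks()
  expect_length(nets, 15)
  expect_identical(unname(vapply(nets, `[[`, integer(1), "input_gene")),
                   1:15)
  g13 <- nets[["gene_13"]]
  expect_equal(g13$roles, c("input", "input", "normal"))
  expect_equal(g13$t_max, 80)
  expect_equal(g13$t_start, 2.48)
  expect_equal(g13$t_end, 51.09)
  expect_equal(g13$alpha, 0.7)
  expect_equal(g13$beta, 0.07)
  expect_equal(g13$t_illum_normal, 2.0)
  expect_identical(g13$output_oscillator, 3L)
  g1 <- nets[["gene_01"]]
  expect_equal(g1$roles, c("input", "normal", "normal"))
  expect_equal(g1$t_illum_normal, c(17.63, 7.24))
  # every network has at least one input and one normal oscillator
  for (nw in nets) {
    expect_true(any(nw$roles == "input") && any(nw$roles == "normal"))
  }
})

test_that("per-table simulation attaches outcomes and normalizes the gene", {
  tab <- toy_patient_table(4)
  cfg <- network_config(roles = c("input", "normal"), input_gene = 1,
                        t_max = 20, t_start = 2, t_end = 15, alpha = 0.3,
                        beta = 0.05, t_illum_normal = 5)
  res <- simulate_table(cfg, tab, coarse_params())
  expect_named(res, c("p", "osc_1", "osc_2", "outcome"))
  expect_equal(res$p, ifelse(tab$outcome == 1, 0.9, 0.1), tolerance = 1e-12)
})
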