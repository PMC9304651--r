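test_that("illumination profile switches between the documented levels", {
  # at the switch time tanh(0) = 0
  expect_equal(illumination(5, 5), 0.1 * 1.001)
  # long after release the level approaches 1e-4
  expect_equal(illumination(1e3, 0), 0.0001, tolerance = 1e-6)
  # well before release it saturates at the suppressing level
  expect_equal(illumination(0, 10), 0.2001, tolerance = 1e-6)
  # strictly decreasing and bounded around the switch (tanh saturates to
  # the limiting levels within double precision further out)
  t <- seq(-1.5, 1.5, by = 0.01)
  phi <- illumination(t, 0)
  expect_true(all(diff(phi) < 0))
  expect_true(all(phi > 0.0001 & phi < 0.2001))
})

test_that("right-hand side matches direct evaluation of the kinetics", {
  p <- oscillator_params()
  # u = q kills the (u - q) factor: du = (q - q^2)/eps, dv = q - v
  d <- oregonator_rhs(u = p$q, v = 0.5, t = 0, params = p, phi = 0)
  expect_equal(d$du, (p$q - p$q^2) / p$epsilon)
  expect_equal(d$du, 0.0066533, tolerance = 1e-4)
  expect_equal(d$dv, p$q - 0.5)
  # all-zero state with no illumination and no coupling is stationary
  d0 <- oregonator_rhs(u = 0, v = 0, t = 0, params = p, phi = 0)
  expect_equal(d0$du, 0)
  expect_equal(d0$dv, 0)
  # at the phi = 0.2 steady state every derivative vanishes
  ss <- steady_state(p, phi = 0.2)
  dss <- oregonator_rhs(u = ss[["u"]], v = ss[["v"]], t = 0, params = p,
                        phi = 0.2)
  expect_lt(abs(dss$du), 1e-8)
  expect_lt(abs(dss$dv), 1e-8)
  # negative activator is an invalid state
  expect_error(oregonator_rhs(u = -0.1, v = 0, t = 0, params = p),
               "invalid state")
})

test_that("steady state solves the nullcline and is dynamically stable", {
  p <- oscillator_params()
  ss <- steady_state(p, phi = 0.2)
  expect_equal(ss[["u"]], 0.00204, tolerance = 1e-4 / 0.00204)
  expect_equal(ss[["v"]], ss[["u"]])
  expect_lt(abs(attr(ss, "residual")), 1e-10)
  # independent root-finding oracle on the same nullcline
  g <- function(u) u - u^2 - (p$f * u + 0.2) * (u - p$q) / (u + p$q)
  oracle <- uniroot(g, c(1e-6, 0.01), tol = 1e-14)$root
  expect_equal(ss[["u"]], oracle, tolerance = 1e-8)
  # f = 0, phi = 0: the stable nontrivial root is u = 1
  expect_equal(steady_state(oscillator_params(f = 1e-12), 0)[["u"]], 1,
               tolerance = 1e-6)
  # strong illumination pins the state to u ~ q
  expect_equal(steady_state(p, phi = 50)[["u"]], p$q, tolerance = 0.05)
  # integrating from the steady state at fixed phi = 0.2 stays put
  traj <- simulate_oscillators(t_illum = 0, t_max = 100, params = p,
                               phi = 0.2, u0 = ss[["u"]], v0 = ss[["v"]])
  expect_lt(max(abs(traj$u - ss[["u"]])), 1e-6)
  expect_lt(max(abs(traj$v - ss[["v"]])), 1e-6)
})

test_that("free-running period and release dynamics match the oscillator physics", {
  expect_equal(measure_period(phi = 0.0001), 8.2, tolerance = 0.1 / 8.2)
  # at suppressing illumination there is no oscillation
  expect_message(res <- measure_period(phi = 0.2), "no oscillation")
  expect_true(is.na(res))
  # period is insensitive to the settling window once past the transient
  p1 <- measure_period(phi = 0.0001, settle_time = 30)
  p2 <- measure_period(phi = 0.0001, settle_time = 45)
  expect_equal(p1, p2, tolerance = 0.02 / 8.2)
  # a released oscillator fits floor(t_max / period) maxima in the window
  traj <- simulate_oscillators(t_illum = 0, t_max = 41)
  expect_identical(attr(traj, "counts"), 5L)
})

test_that("peak counting is exact on constructed waveforms", {
  # constant at the suppressed level: no maxima
  expect_identical(count_maxima(rep(0.00204, 1000)), 0L)
  # 3 full sine periods riding above threshold
  x <- 0.1 + 0.04 * sin(seq(0, 6 * pi, length.out = 3000))
  expect_identical(count_maxima(x), 3L)
  # threshold above the maximum kills every peak
  expect_identical(count_maxima(x, threshold = 0.2), 0L)
  # plateaus count once, at the leftmost sample
  expect_identical(count_maxima(c(0, 1, 1, 1, 0), threshold = 0.5), 1L)
  # compiled counter agrees with the R scan on a real trajectory
  traj <- simulate_oscillators(t_illum = c(2, 7), t_max = 50, alpha = 0.1,
                               beta = 0.05)
  expect_identical(count_maxima(traj)$n_maxima, attr(traj, "counts"))
})

test_that("coupled integration respects exact structural symmetries", {
  # identical oscillators, all-to-all coupling: trajectories coincide
  tr <- simulate_oscillators(t_illum = c(3, 3, 3), t_max = 30, alpha = 0.2,
                             beta = 0.05)
  u <- matrix(tr$u, ncol = 3)
  expect_lt(max(abs(u[, 1] - u[, 2])), 1e-9)
  expect_lt(max(abs(u[, 1] - u[, 3])), 1e-9)
  # decoupled limit reproduces isolated single-oscillator runs
  tr2 <- simulate_oscillators(t_illum = c(4, 9), t_max = 30, alpha = 0,
                              beta = 0)
  for (j in 1:2) {
    iso <- simulate_oscillators(t_illum = c(4, 9)[j], t_max = 30)
    expect_lt(max(abs(tr2$u[tr2$oscillator == j] - iso$u)), 1e-9)
  }
  # permutation symmetry: relabeling oscillators permutes trajectories
  till <- c(2, 6, 11)
  perm <- c(3, 1, 2)
  tra <- simulate_oscillators(t_illum = till, t_max = 25, alpha = 0.3,
                              beta = 0.04)
  trb <- simulate_oscillators(t_illum = till[perm], t_max = 25, alpha = 0.3,
                              beta = 0.04)
  ua <- matrix(tra$u, ncol = 3)
  ub <- matrix(trb$u, ncol = 3)
  for (j in 1:3) expect_lt(max(abs(ua[, perm[j]] - ub[, j])), 1e-12)
})

test_that("peak counts grow monotonically with the observation horizon", {
  horizons <- c(10, 20, 35, 50, 70)
  counts <- vapply(horizons, function(tm) {
    attr(simulate_oscillators(t_illum = 1.5, t_max = tm), "counts")
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("integration error is at the scheme's order and sampling-robust", {
  # halving dt changes the endpoint state negligibly (5th-order scheme)
  end_u <- function(dt) {
    tr <- simulate_oscillators(t_illum = 1, t_max = 20,
                               params = oscillator_params(dt = dt),
                               record_stride = 1)
    tail(tr$u, 1)
  }
  expect_lt(abs(end_u(1e-3) - end_u(5e-4)), 1e-8)
  # peak counts are unchanged between stride 10 and stride 1
  tr10 <- simulate_oscillators(t_illum = 1, t_max = 50, record_stride = 10)
  tr1 <- simulate_oscillators(t_illum = 1, t_max = 50, record_stride = 1)
  expect_identical(attr(tr10, "counts"), attr(tr1, "counts"))
  # counts at the coarse exploratory step equal the reference step
  cfg <- published_networks(13)[[1]]
  cfg$t_max <- 20
  p <- seq(0, 1, 0.1)
  expect_identical(simulate_network(cfg, p, oscillator_params(dt = 1e-3)),
                   simulate_network(cfg, p, coarse_params()))
})

test_that("trajectories agree with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  p <- oscillator_params()
  till <- c(2, 5)
  f <- function(t, y, parms) {
    d <- oregonator_rhs(u = y[1:2], v = y[3:4], t = t, params = p,
                        t_illum = till, alpha = 0.15, beta = 0.03)
    list(c(d$du, d$dv))
  }
  y0 <- rep(steady_state(p, illumination(0, 2))[["u"]], 4)
  ref <- deSolve::lsoda(y0, seq(0, 15, 0.01), f, NULL, rtol = 1e-10,
                        atol = 1e-12)
  tr <- simulate_oscillators(t_illum = till, t_max = 15, alpha = 0.15,
                             beta = 0.03)
  u <- matrix(tr$u, ncol = 2)
  expect_lt(max(abs(u[, 1] - ref[, 2])), 1e-5)
  expect_lt(max(abs(u[, 2] - ref[, 3])), 1e-5)
})

test_that("adaptive mode reproduces the fixed-step readout", {
  for (till in c(1, 6)) {
    fixed <- simulate_oscillators(t_illum = till, t_max = 40)
    adapt <- simulate_oscillators(t_illum = till, t_max = 40,
                                  adaptive = TRUE, record_stride = 1)
    expect_identical(attr(adapt, "counts"), attr(fixed, "counts"))
  }
})

test_that("trajectory export and plotting round-trip the tidy layout", {
  tr <- simulate_oscillators(t_illum = c(1, 4), t_max = 10)
  expect_true(all(tr$u >= 0) && all(tr$v >= 0))
  expect_identical(tr$time[1], 0)
  expect_equal(max(tr$time), 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tr))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
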