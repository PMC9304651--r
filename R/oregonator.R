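#' Oregonator model constants
#'
#' Bundles the kinetic constants of the two-variable photosensitive
#' Oregonator together with the readout threshold and integration step.
#' The defaults are the values used throughout the classifier study:
#' `epsilon = 0.3` (time-scale ratio between activator and inhibitor),
#' `q = 0.002` (scaling constant), `f = 1.1` (stoichiometric coefficient),
#' a peak threshold of 0.05 on the activator, and a fixed integration step
#' of `1e-3` model time units.
#'
#' @param epsilon Time-scale ratio between the activator u and inhibitor v
#'   dynamics; dimensionless, must be positive.
#' @param q Scaling constant of the Oregonator kinetics; dimensionless.
#' @param f Stoichiometric coefficient; dimensionless.
#' @param peak_threshold Activator level a local maximum must exceed to be
#'   counted by the readout.
#' @param dt Fixed integration step in model time units.
#' @return An object of class `oscillator_params`.
#' @examples
#' oscillator_params()
#' oscillator_params(f = 2 / 3)
#' @export
oscillator_params <- function(epsilon = 0.3, q = 0.002, f = 1.1,
                              peak_threshold = 0.05, dt = 1e-3) {
  for (nm in c("epsilon", "q", "f", "peak_threshold", "dt")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      abort(sprintf("`%s` must be a single positive number", nm))
  }
  structure(
    list(epsilon = epsilon, q = q, f = f,
         peak_threshold = peak_threshold, dt = dt),
    class = "oscillator_params"
  )
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>",
      sprintf("epsilon = %g, q = %g, f = %g", x$epsilon, x$q, x$f),
      sprintf("peak threshold = %g, dt = %g", x$peak_threshold, x$dt),
      sep = "\n")
  invisible(x)
}

#' Illumination profile of an oscillator
#'
#' The light intensity applied to an oscillator follows
#' \deqn{\phi(t) = 0.1\,[1.001 + \tanh(-10 (t - t_{illum}))],}
#' a smooth switch from the suppressing level (about 0.2001) to the
#' oscillatory level (about 0.0001) around the release time `t_illum`.
#' High illumination holds the photosensitive Belousov-Zhabotinsky medium in
#' a stable steady state; once it drops, oscillations start.
#'
#' @param t Time(s) in model units; any real value is allowed.
#' @param t_illum Switch time(s) in model units; recycled against `t`.
#' @return Illumination value(s), strictly decreasing in `t` and bounded in
#'   (0.0001, 0.2001) for finite times.
#' @examples
#' illumination(0, 5)        # still suppressed
#' illumination(100, 5)      # released: ~1e-4
#' @export
illumination <- function(t, t_illum) {
  0.1 * (1.001 + tanh(-10 * (t - t_illum)))
}

#' Right-hand side of the coupled Oregonator network
#'
#' Time derivatives of activator `u` and inhibitor `v` for `m` oscillators
#' coupled by activator exchange:
#' \deqn{du_j/dt = \frac{1}{\varepsilon}\left[u_j - u_j^2 -
#'   (f v_j + \phi_j(t))\frac{u_j - q}{u_j + q}\right]
#'   - (\alpha + \beta \textstyle\sum_i s_{ji}) u_j + \beta \sum_i s_{ji} u_i}
#' \deqn{dv_j/dt = u_j - v_j}
#' With `alpha = beta = 0` this reduces exactly to `m` independent
#' single-oscillator Oregonators. This pure-R evaluation is the reference
#' form of the model; the integrator uses an identical compiled version.
#'
#' @param u,v Activator and inhibitor concentrations, one value per
#'   oscillator. Must be non-negative.
#' @param t Time in model units.
#' @param params An [oscillator_params()] object.
#' @param t_illum Per-oscillator switch times (recycled).
#' @param coupling Symmetric 0/1 matrix with zero diagonal; `NULL` means
#'   all-to-all for `m > 1`, no coupling for `m = 1`.
#' @param alpha Lumped activator decay rate (>= 0).
#' @param beta Lumped activator exchange rate (>= 0).
#' @param phi Optional fixed illumination per oscillator overriding the
#'   time-dependent profile (recycled; `NA` entries fall back to the
#'   profile).
#' @return A list with components `du` and `dv`.
#' @examples
#' p <- oscillator_params()
#' oregonator_rhs(u = p$q, v = 0, t = 0, params = p, phi = 0)
#' @export
oregonator_rhs <- function(u, v, t, params = oscillator_params(),
                           t_illum = 0, coupling = NULL, alpha = 0, beta = 0,
                           phi = NULL) {
  m <- length(u)
  stopifnot(length(v) == m)
  if (any(u < 0))
    abort("negative activator concentration: invalid state")
  if (alpha < 0 || beta < 0)
    abort("`alpha` and `beta` must be non-negative")
  S <- check_coupling(coupling, m)
  t_illum <- rep_len(t_illum, m)
  phi_j <- if (is.null(phi)) illumination(t, t_illum) else {
    ph <- rep_len(phi, m)
    ifelse(is.na(ph), illumination(t, t_illum), ph)
  }
  deg <- rowSums(S)
  core <- (u - u^2 - (params$f * v + phi_j) * (u - params$q) /
             (u + params$q)) / params$epsilon
  du <- core - (alpha + beta * deg) * u + beta * as.vector(S %*% u)
  dv <- u - v
  list(du = du, dv = dv)
}

check_coupling <- function(coupling, m) {
  if (is.null(coupling)) {
    S <- matrix(1L, m, m) - diag(1L, m)
  } else {
    S <- coupling
    if (!is.matrix(S) || nrow(S) != m || ncol(S) != m)
      abort("`coupling` must be an m x m matrix")
    if (any(S != t(S)) || any(diag(S) != 0) || !all(S %in% c(0, 1)))
      abort("`coupling` must be a symmetric 0/1 matrix with zero diagonal")
  }
  storage.mode(S) <- "integer"
  S
}

#' Stable steady state of a single oscillator at fixed illumination
#'
#' Finds the stable stationary point of the uncoupled Oregonator at constant
#' illumination `phi`: the root of
#' `u - u^2 - (f u + phi)(u - q)/(u + q) = 0` (with `v* = u*`) at which the
#' Jacobian has negative trace and positive determinant. At the reference
#' constants and `phi = 0.2` this is `u* = v* = 0.00204`, the state in which
#' every oscillator is held before its illumination is switched off.
#'
#' @inheritParams oregonator_rhs
#' @param phi Fixed illumination level (>= 0).
#' @return Named numeric vector `c(u = , v = )` with attribute `"residual"`.
#'   Errors if no stable root exists in (0, 1.1) -- e.g. in the oscillatory
#'   regime at very low illumination.
#' @examples
#' steady_state(oscillator_params(), phi = 0.2)
#' @export
steady_state <- function(params = oscillator_params(), phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0)
  res <- cpp_steady_state(params$epsilon, params$q, params$f, phi)
  if (!res$found)
    abort(sprintf("no stable steady state in (0, 1.1) at phi = %g", phi))
  structure(c(u = res$u, v = res$v), residual = res$residual)
}

#' Integrate a network of photosensitive Oregonator oscillators
#'
#' Solves the coupled network equations over `[0, t_max]` with the 5th-order
#' Cash-Karp scheme at fixed step `params$dt` (the reference mode), or with
#' embedded-error adaptive stepping. Unless `u0`/`v0` are given, every
#' oscillator starts at the stable steady state of its own initial
#' illumination `phi_j(0)`, i.e. fully suppressed.
#'
#' @inheritParams oregonator_rhs
#' @param t_illum Per-oscillator illumination switch times (model time units);
#'   its length sets the number of oscillators unless `u0` is given.
#' @param t_max Observation horizon in model time units (> 0).
#' @param u0,v0 Optional explicit initial state per oscillator.
#' @param record_stride Record every `record_stride`-th accepted step
#'   (default 10, i.e. every 0.01 time units at the default `dt`); the final
#'   time `t_max` is always recorded.
#' @param adaptive Use adaptive step-size control instead of the fixed-step
#'   reference mode.
#' @param abstol,reltol Error tolerances for the adaptive mode.
#' @return A tibble of class `osc_trajectory` with columns `time`,
#'   `oscillator`, `u`, `v`, and attributes `counts` (supra-threshold maxima
#'   per oscillator) and `params`.
#' @examples
#' traj <- simulate_oscillators(t_illum = 0, t_max = 20)
#' attr(traj, "counts")
#' @export
simulate_oscillators <- function(t_illum, t_max,
                                 params = oscillator_params(),
                                 coupling = NULL, alpha = 0, beta = 0,
                                 phi = NULL, u0 = NULL, v0 = NULL,
                                 record_stride = 10, adaptive = FALSE,
                                 abstol = 1e-9, reltol = 1e-7) {
  stopifnot(t_max > 0)
  m <- if (!is.null(u0)) length(u0) else length(t_illum)
  t_illum <- rep_len(as.numeric(t_illum), m)
  phi_fixed <- if (is.null(phi)) rep(NA_real_, m) else rep_len(as.numeric(phi), m)
  S <- check_coupling(coupling, m)
  if (is.null(u0)) {
    init <- vapply(seq_len(m), function(j) {
      phi0 <- if (!is.na(phi_fixed[j])) phi_fixed[j] else
        illumination(0, t_illum[j])
      # oscillators already released at t = 0 have no stable state; start
      # them on the (unstable) nullcline root, as the batch simulator does
      res <- cpp_steady_state(params$epsilon, params$q, params$f, phi0,
                              FALSE)
      if (!res$found)
        abort(sprintf("no steady state found at phi(0) = %g", phi0))
      res$u
    }, numeric(1))
    u0 <- init
    v0 <- init
  }
  if (is.null(v0)) v0 <- u0
  res <- cpp_integrate(as.numeric(u0), as.numeric(v0), t_illum, phi_fixed,
                       params$epsilon, params$q, params$f, alpha, beta, S,
                       t_max, params$dt, as.integer(record_stride),
                       params$peak_threshold, TRUE, adaptive, abstol, reltol)
  n <- length(res$times)
  out <- tibble(
    time = rep(res$times, times = m),
    oscillator = rep(seq_len(m), each = n),
    u = as.vector(res$u),
    v = as.vector(res$v)
  )
  attr(out, "counts") <- res$counts
  attr(out, "params") <- params
  class(out) <- c("osc_trajectory", class(out))
  out
}

#' Count supra-threshold activator maxima
#'
#' The classifier readout: the number of strict local maxima of the
#' activator that exceed the threshold. A sample counts when it is strictly
#' above its predecessor and at least its successor (so a flat-topped
#' plateau counts once, at its leftmost sample).
#'
#' @param x A numeric activator series, or an `osc_trajectory` tibble from
#'   [simulate_oscillators()] (counted per oscillator).
#' @param threshold Activator level a maximum must exceed (default 0.05).
#' @return For a numeric series, a single count; for a trajectory, a tibble
#'   with columns `oscillator` and `n_maxima`.
#' @examples
#' count_maxima(0.1 + 0.04 * sin(seq(0, 6 * pi, by = 0.01)))
#' @export
count_maxima <- function(x, threshold = 0.05) {
  stopifnot(threshold > 0)
  if (inherits(x, "osc_trajectory") || (is.data.frame(x) && "oscillator" %in% names(x))) {
    return(
      as_tibble(x) |>
        group_by(.data$oscillator) |>
        arrange(.data$time, .by_group = TRUE) |>
        summarise(n_maxima = count_maxima_vec(.data$u, threshold),
                  .groups = "drop")
    )
  }
  count_maxima_vec(as.numeric(x), threshold)
}

count_maxima_vec <- function(u, threshold) {
  n <- length(u)
  if (n < 3L) return(0L)
  mid <- u[2:(n - 1)]
  sum(u[1:(n - 2)] < mid & mid >= u[3:n] & mid > threshold)
}

#' Measure the free-running oscillation period
#'
#' Integrates a single oscillator at a fixed illumination level, discards a
#' settling transient, and returns the mean interval between successive
#' supra-threshold activator maxima. At the reference constants and
#' `phi = 0.0001` (the long-time illumination of a released oscillator) the
#' period is 8.2 model time units.
#'
#' @inheritParams steady_state
#' @param settle_time Transient discarded before measuring (default 30).
#' @param measure_time Length of the measurement window (default 50).
#' @return The mean inter-peak interval in model time units, or `NA_real_`
#'   (with a message) when fewer than two peaks occur in the window -- the
#'   "no oscillation" verdict.
#' @examples
#' measure_period(phi = 0.0001)
#' @export
measure_period <- function(params = oscillator_params(), phi,
                           settle_time = 30, measure_time = 50) {
  stopifnot(settle_time > 0, measure_time > 0)
  # Start from the fully illuminated (suppressed) state, then run at fixed phi
  ss <- steady_state(params, 0.2)
  traj <- simulate_oscillators(t_illum = 0, t_max = settle_time + measure_time,
                               params = params, phi = phi,
                               u0 = ss[["u"]], v0 = ss[["v"]])
  tt <- traj$time
  uu <- traj$u
  n <- length(uu)
  is_peak <- c(FALSE,
               uu[2:(n - 1)] > uu[1:(n - 2)] & uu[2:(n - 1)] >= uu[3:n] &
                 uu[2:(n - 1)] > params$peak_threshold,
               FALSE)
  pk <- tt[is_peak & tt >= settle_time]
  if (length(pk) < 2L) {
    message("no oscillation: fewer than 2 peaks in the measurement window")
    return(NA_real_)
  }
  mean(diff(pk))
}

#' Export a trajectory to tidy CSV
#'
#' Writes the columns `time`, `oscillator`, `u`, `v` of a simulated
#' trajectory, mainly for external inspection of network dynamics.
#'
#' @param traj An `osc_trajectory` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(as_tibble(traj)[, c("time", "oscillator", "u", "v")], path)
  invisible(path)
}
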