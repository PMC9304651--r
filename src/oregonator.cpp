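// Two-variable photosensitive Oregonator: coupled-network right-hand side,
// fixed-step (and optional adaptive) 5th-order Cash-Karp integration,
// on-the-fly supra-threshold peak counting, and steady-state root finding.
//
// The hot path is the evolutionary search, which needs ~1e6 network
// integrations; everything here is allocation-free inside the step loop.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// Illumination profile: phi(t) = 0.1 * (1.001 + tanh(-10 (t - t_illum))).
// tanh saturates to +/-1 in double precision well before |arg| = 20, so the
// expensive call is skipped outside a narrow window around t_illum.
static inline double phi_illum(double t, double t_illum) {
  double arg = -10.0 * (t - t_illum);
  if (arg > 20.0) return 0.1 * 2.001;
  if (arg < -20.0) return 0.1 * 0.001;
  return 0.1 * (1.001 + std::tanh(arg));
}

// Oregonator nullcline residual at v = u for fixed illumination phi:
// g(u) = u - u^2 - (f u + phi)(u - q)/(u + q).  Steady states are its roots.
static inline double steady_resid(double u, double q, double f, double phi) {
  return u - u * u - (f * u + phi) * (u - q) / (u + q);
}

// Stability of a steady state (u*, v* = u*) of the uncoupled system:
// Jacobian [[J11, J12], [1, -1]] must have trace < 0 and det > 0.
static bool steady_stable(double u, double eps, double q, double f,
                          double phi) {
  double G = (u - q) / (u + q);
  double dG = 2.0 * q / ((u + q) * (u + q));
  double J11 = (1.0 - 2.0 * u - (f * u + phi) * dG) / eps;
  double J12 = -(f / eps) * G;
  double tr = J11 - 1.0;
  double det = -J11 - J12;
  return tr < 0.0 && det > 0.0;
}

// Scan (lo, hi) for sign changes of the nullcline residual, refine each by
// bisection, and return the stable root.  Scanning is log-spaced because the
// suppressed-state root sits near q while the f = 0 root sits at 1.
static double steady_root(double eps, double q, double f, double phi,
                          bool& stable_found, double& any_root) {
  const int n_scan = 800;
  const double lo = 1e-9, hi = 1.1;
  double log_lo = std::log(lo), log_hi = std::log(hi);
  double u_prev = lo, g_prev = steady_resid(lo, q, f, phi);
  stable_found = false;
  any_root = NA_REAL;
  for (int i = 1; i <= n_scan; ++i) {
    double u = std::exp(log_lo + (log_hi - log_lo) * i / n_scan);
    double g = steady_resid(u, q, f, phi);
    if (g == 0.0 || g_prev * g < 0.0) {
      double a = u_prev, b = u;
      for (int it = 0; it < 200; ++it) {
        double mid = 0.5 * (a + b);
        double gm = steady_resid(mid, q, f, phi);
        if (g_prev * gm <= 0.0) b = mid; else a = mid;
        if (b - a < 1e-16 * (1.0 + b)) break;
      }
      double root = 0.5 * (a + b);
      if (ISNAN(any_root)) any_root = root;
      if (steady_stable(root, eps, q, f, phi)) {
        stable_found = true;
        return root;
      }
    }
    u_prev = u;
    g_prev = g;
  }
  return NA_REAL;
}

// [[Rcpp::export]]
List cpp_steady_state(double eps, double q, double f, double phi,
                      bool require_stable = true) {
  bool stable;
  double any;
  double u = steady_root(eps, q, f, phi, stable, any);
  if (!stable && !require_stable && !ISNAN(any)) u = any;
  bool found = stable || (!require_stable && !ISNAN(any));
  return List::create(_["u"] = u, _["v"] = u, _["found"] = found,
                      _["stable"] = stable,
                      _["residual"] = found ? steady_resid(u, q, f, phi)
                                            : NA_REAL);
}

struct NetRHS {
  int m;
  double eps, q, f, alpha, beta;
  const int* S;                 // m x m, column-major
  const double* till;           // per-oscillator t_illum
  const double* phi_fixed;      // NA -> time-dependent illumination
  std::vector<double> deg;      // row sums of S

  void init_deg() {
    deg.assign(m, 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i) deg[j] += S[j + m * i];
  }

  void operator()(double t, const double* __restrict u,
                  const double* __restrict v, double* __restrict du,
                  double* __restrict dv) const {
    const double inv_eps = 1.0 / eps, qq = q, ff = f, al = alpha, be = beta;
    const int mm = m;
    const int* __restrict Sp = S;
    const double* __restrict dg = deg.data();
    for (int j = 0; j < mm; ++j) {
      double phi = ISNAN(phi_fixed[j]) ? phi_illum(t, till[j]) : phi_fixed[j];
      double uj = u[j];
      double core = (uj - uj * uj -
                     (ff * v[j] + phi) * (uj - qq) / (uj + qq)) * inv_eps;
      double cpl = 0.0;
      for (int i = 0; i < mm; ++i)
        cpl += Sp[j + mm * i] * u[i];
      du[j] = core - (al + be * dg[j]) * uj + be * cpl;
      dv[j] = uj - v[j];
    }
  }
};

// Cash-Karp tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 3.0 / 5, c5 = 1.0,
                    c6 = 7.0 / 8;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 3.0 / 10, a42 = -9.0 / 10, a43 = 6.0 / 5;
static const double a51 = -11.0 / 54, a52 = 5.0 / 2, a53 = -70.0 / 27,
                    a54 = 35.0 / 27;
static const double a61 = 1631.0 / 55296, a62 = 175.0 / 512,
                    a63 = 575.0 / 13824, a64 = 44275.0 / 110592,
                    a65 = 253.0 / 4096;
static const double b1 = 37.0 / 378, b3 = 250.0 / 621, b4 = 125.0 / 594,
                    b6 = 512.0 / 1771;
static const double e1 = 37.0 / 378 - 2825.0 / 27648,
                    e3 = 250.0 / 621 - 18575.0 / 48384,
                    e4 = 125.0 / 594 - 13525.0 / 55296,
                    e5 = -277.0 / 14336, e6 = 512.0 / 1771 - 1.0 / 4;

// One Cash-Karp step for the 2m-dimensional state; returns the embedded
// 4th/5th-order error estimate scaled by (abstol + reltol * |y|).
struct Stepper {
  NetRHS rhs;
  int m;
  std::vector<double> k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v, k5u, k5v, k6u,
      k6v, tu, tv;

  explicit Stepper(const NetRHS& r) : rhs(r), m(r.m) {
    k1u.resize(m); k1v.resize(m); k2u.resize(m); k2v.resize(m);
    k3u.resize(m); k3v.resize(m); k4u.resize(m); k4v.resize(m);
    k5u.resize(m); k5v.resize(m); k6u.resize(m); k6v.resize(m);
    tu.resize(m); tv.resize(m);
  }

  double step(double t, double h, const double* __restrict u,
              const double* __restrict v, double* __restrict u_out,
              double* __restrict v_out, double abstol, double reltol) {
    const int mm = m;
    double* __restrict K1u = k1u.data(); double* __restrict K1v = k1v.data();
    double* __restrict K2u = k2u.data(); double* __restrict K2v = k2v.data();
    double* __restrict K3u = k3u.data(); double* __restrict K3v = k3v.data();
    double* __restrict K4u = k4u.data(); double* __restrict K4v = k4v.data();
    double* __restrict K5u = k5u.data(); double* __restrict K5v = k5v.data();
    double* __restrict K6u = k6u.data(); double* __restrict K6v = k6v.data();
    double* __restrict Tu = tu.data();   double* __restrict Tv = tv.data();

    rhs(t, u, v, K1u, K1v);
    for (int j = 0; j < mm; ++j) {
      Tu[j] = u[j] + h * a21 * K1u[j];
      Tv[j] = v[j] + h * a21 * K1v[j];
    }
    rhs(t + c2 * h, Tu, Tv, K2u, K2v);
    for (int j = 0; j < mm; ++j) {
      Tu[j] = u[j] + h * (a31 * K1u[j] + a32 * K2u[j]);
      Tv[j] = v[j] + h * (a31 * K1v[j] + a32 * K2v[j]);
    }
    rhs(t + c3 * h, Tu, Tv, K3u, K3v);
    for (int j = 0; j < mm; ++j) {
      Tu[j] = u[j] + h * (a41 * K1u[j] + a42 * K2u[j] + a43 * K3u[j]);
      Tv[j] = v[j] + h * (a41 * K1v[j] + a42 * K2v[j] + a43 * K3v[j]);
    }
    rhs(t + c4 * h, Tu, Tv, K4u, K4v);
    for (int j = 0; j < mm; ++j) {
      Tu[j] = u[j] +
              h * (a51 * K1u[j] + a52 * K2u[j] + a53 * K3u[j] + a54 * K4u[j]);
      Tv[j] = v[j] +
              h * (a51 * K1v[j] + a52 * K2v[j] + a53 * K3v[j] + a54 * K4v[j]);
    }
    rhs(t + c5 * h, Tu, Tv, K5u, K5v);
    for (int j = 0; j < mm; ++j) {
      Tu[j] = u[j] + h * (a61 * K1u[j] + a62 * K2u[j] + a63 * K3u[j] +
                          a64 * K4u[j] + a65 * K5u[j]);
      Tv[j] = v[j] + h * (a61 * K1v[j] + a62 * K2v[j] + a63 * K3v[j] +
                          a64 * K4v[j] + a65 * K5v[j]);
    }
    rhs(t + c6 * h, Tu, Tv, K6u, K6v);
    double err = 0.0;
    for (int j = 0; j < mm; ++j) {
      u_out[j] = u[j] + h * (b1 * K1u[j] + b3 * K3u[j] + b4 * K4u[j] +
                             b6 * K6u[j]);
      v_out[j] = v[j] + h * (b1 * K1v[j] + b3 * K3v[j] + b4 * K4v[j] +
                             b6 * K6v[j]);
      if (reltol > 0.0 || abstol != 1.0) {
        double eu = h * (e1 * K1u[j] + e3 * K3u[j] + e4 * K4u[j] +
                         e5 * K5u[j] + e6 * K6u[j]);
        double ev = h * (e1 * K1v[j] + e3 * K3v[j] + e4 * K4v[j] +
                         e5 * K5v[j] + e6 * K6v[j]);
        double su = abstol + reltol * std::fabs(u_out[j]);
        double sv = abstol + reltol * std::fabs(v_out[j]);
        err = std::max(err, std::fabs(eu) / su);
        err = std::max(err, std::fabs(ev) / sv);
      }
    }
    return err;
  }
};

// Strict-local-maximum peak tracker on the recorded grid: a sample counts
// when prev < cur >= next and cur > threshold; a flat-topped plateau counts
// once, at its leftmost sample.
struct PeakCounter {
  int m;
  double threshold;
  std::vector<double> prev1, prev2;  // prev1 = last sample, prev2 = one before
  std::vector<int> n_seen, counts;

  PeakCounter(int m_, double thr) : m(m_), threshold(thr) {
    prev1.assign(m, 0.0);
    prev2.assign(m, 0.0);
    n_seen.assign(m, 0);
    counts.assign(m, 0);
  }

  void push(const double* u) {
    for (int j = 0; j < m; ++j) {
      if (n_seen[j] >= 2 && prev2[j] < prev1[j] && prev1[j] >= u[j] &&
          prev1[j] > threshold)
        counts[j]++;
      prev2[j] = prev1[j];
      prev1[j] = u[j];
      n_seen[j]++;
    }
  }
};

// Full network integration over [0, t_max] from a caller-supplied initial
// state.  Fixed-step mode advances with constant dt (last step truncated to
// land on t_max exactly); adaptive mode uses the embedded error estimate.
// Peaks are counted on the recorded grid (every `stride`-th accepted step).
// [[Rcpp::export]]
List cpp_integrate(NumericVector u0, NumericVector v0, NumericVector till,
                   NumericVector phi_fixed, double eps, double q, double f,
                   double alpha, double beta, IntegerMatrix S, double t_max,
                   double dt, int stride, double threshold, bool return_traj,
                   bool adaptive, double abstol, double reltol) {
  int m = u0.size();
  NetRHS rhs;
  rhs.m = m;
  rhs.eps = eps; rhs.q = q; rhs.f = f;
  rhs.alpha = alpha; rhs.beta = beta;
  rhs.S = S.begin();
  rhs.till = till.begin();
  rhs.phi_fixed = phi_fixed.begin();
  rhs.init_deg();
  Stepper stepper(rhs);
  PeakCounter peaks(m, threshold);

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> un(m), vn(m);
  std::vector<double> rec_t;
  std::vector<double> rec_u, rec_v;  // row-major: sample-major blocks of m

  double t = 0.0;
  long step_no = 0;
  auto record = [&](double tt, const double* uu, const double* vv) {
    peaks.push(uu);
    if (return_traj) {
      rec_t.push_back(tt);
      for (int j = 0; j < m; ++j) rec_u.push_back(uu[j]);
      for (int j = 0; j < m; ++j) rec_v.push_back(vv[j]);
    }
  };
  record(t, u.data(), v.data());

  const double tiny = 1e-12;
  if (!adaptive) {
    // walk an exact step-index grid (t = k * dt) so the recorded times are
    // free of accumulation drift; a final partial step lands on t_max
    long n_full = (long)std::floor(t_max / dt + 1e-9);
    double rem = t_max - n_full * dt;
    for (long k = 1; k <= n_full; ++k) {
      double t0 = (k - 1) * dt;
      stepper.step(t0, dt, u.data(), v.data(), un.data(), vn.data(), 1.0,
                   0.0);
      u.swap(un);
      v.swap(vn);
      bool last = (k == n_full) && rem <= tiny;
      if (k % stride == 0 || last) record(k * dt, u.data(), v.data());
      for (int j = 0; j < m; ++j)
        if (!std::isfinite(u[j]) || !std::isfinite(v[j]))
          stop("non-finite state at t = %f: integration blow-up", k * dt);
    }
    if (rem > tiny) {
      stepper.step(n_full * dt, rem, u.data(), v.data(), un.data(),
                   vn.data(), 1.0, 0.0);
      u.swap(un);
      v.swap(vn);
      for (int j = 0; j < m; ++j)
        if (!std::isfinite(u[j]) || !std::isfinite(v[j]))
          stop("non-finite state at t = %f: integration blow-up", t_max);
      record(t_max, u.data(), v.data());
    }
  } else {
    double h = dt;
    while (t < t_max - tiny) {
      if (t + h > t_max) h = t_max - t;
      double err = stepper.step(t, h, u.data(), v.data(), un.data(),
                                vn.data(), abstol, reltol);
      if (err <= 1.0) {
        t += h;
        u.swap(un);
        v.swap(vn);
        step_no++;
        if (step_no % stride == 0 || t >= t_max - tiny)
          record(t, u.data(), v.data());
        h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(err + 1e-30, -0.2)));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
        if (h < 1e-12)
          stop("adaptive step size underflow: integration failure");
      }
      for (int j = 0; j < m; ++j)
        if (!std::isfinite(u[j]) || !std::isfinite(v[j]))
          stop("non-finite state at t = %f: integration blow-up", t);
    }
  }

  List out = List::create(_["counts"] = IntegerVector(peaks.counts.begin(),
                                                      peaks.counts.end()));
  if (return_traj) {
    int n = rec_t.size();
    NumericMatrix U(n, m), V(n, m);
    for (int k = 0; k < n; ++k)
      for (int j = 0; j < m; ++j) {
        U(k, j) = rec_u[(size_t)k * m + j];
        V(k, j) = rec_v[(size_t)k * m + j];
      }
    out["times"] = NumericVector(rec_t.begin(), rec_t.end());
    out["u"] = U;
    out["v"] = V;
  }
  return out;
}

// Batch simulation for training: one row of `till` per record, standard
// initial condition (each oscillator at the stable steady state of its own
// phi_j(0), memoized on the phi value).  Returns per-record, per-oscillator
// supra-threshold maxima counts.
// [[Rcpp::export]]
IntegerMatrix cpp_counts_batch(NumericMatrix till, double eps, double q,
                               double f, double alpha, double beta,
                               IntegerMatrix S, double t_max, double dt,
                               int stride, double threshold) {
  int n = till.nrow(), m = till.ncol();
  IntegerMatrix counts(n, m);
  std::map<double, double> ss_cache;
  NumericVector phi_na(m, NA_REAL);

  for (int r = 0; r < n; ++r) {
    NumericVector t_row(m), u0(m), v0(m);
    for (int j = 0; j < m; ++j) {
      t_row[j] = till(r, j);
      double phi0 = phi_illum(0.0, t_row[j]);
      auto it = ss_cache.find(phi0);
      double ss;
      if (it == ss_cache.end()) {
        bool stable;
        double any;
        ss = steady_root(eps, q, f, phi0, stable, any);
        // An oscillator already released at t = 0 (phi(0) in the oscillatory
        // regime) has no stable state; start it on the unstable nullcline
        // root, from which oscillations develop at once.
        if (!stable) ss = any;
        if (ISNAN(ss))
          stop("no steady state found at phi(0) = %f; cannot initialize",
               phi0);
        ss_cache[phi0] = ss;
      } else {
        ss = it->second;
      }
      u0[j] = ss;
      v0[j] = ss;
    }
    List res = cpp_integrate(u0, v0, t_row, phi_na, eps, q, f, alpha, beta, S,
                             t_max, dt, stride, threshold, false, false, 0.0,
                             0.0);
    IntegerVector cts = res["counts"];
    for (int j = 0; j < m; ++j) counts(r, j) = cts[j];
  }
  return counts;
}
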