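// Wiener first-passage-time (WFPT) likelihood kernel and diffusion simulator.
//
// Conventions: diffusion coefficient fixed at 1; accuracy coding, so the
// upper boundary is the correct response. Internally everything is in
// seconds; callers convert from ms once at the I/O boundary.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64 seeding + xoroshiro128+), so simulated
// datasets are reproducible from a single integer seed independently of R's
// RNG state.

namespace {

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers)
struct ZigTables {
  double x[129];   // decreasing: x[0] = base edge, x[1] = r, ..., x[128] = 0
  double y[129];   // y[i] = exp(-x[i]^2 / 2), increasing to 1
  ZigTables() {
    const double r = 3.442619855899;
    const double v = 9.91256303526217e-3;
    x[0] = v / std::exp(-0.5 * r * r);
    x[1] = r;
    for (int i = 2; i < 128; ++i) {
      x[i] = std::sqrt(-2.0 * std::log(v / x[i - 1] + std::exp(-0.5 * x[i - 1] * x[i - 1])));
    }
    x[128] = 0.0;
    for (int i = 0; i <= 128; ++i) y[i] = std::exp(-0.5 * x[i] * x[i]);
  }
};
static const ZigTables zig;

struct Rng {
  uint64_t s0, s1;
  bool have_cached;
  double cached;

  explicit Rng(uint64_t seed) : have_cached(false), cached(0.0) {
    // splitmix64 to spread a small seed over the full state
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 2; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      z = z ^ (z >> 31);
      if (i == 0) s0 = z; else s1 = z;
    }
    if (s0 == 0 && s1 == 0) s0 = 1;
  }

  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }

  // uniform on (0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.6e-17;
  }

  // standard normal via the ziggurat method (Box-Muller fallback in the tail)
  inline double norm() {
    for (;;) {
      uint64_t bits = next();
      int idx = (int)(bits & 127);
      double sign = (bits & 128) ? 1.0 : -1.0;
      double u = ((bits >> 11) * (1.0 / 9007199254740992.0));
      double xcand = u * zig.x[idx];
      if (xcand < zig.x[idx + 1]) return sign * xcand;
      if (idx == 0) {
        // tail beyond r: Marsaglia's exact tail sampler
        const double r = 3.442619855899;
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return sign * (r + xx);
      }
      double fy = zig.y[idx] + unif() * (zig.y[idx + 1] - zig.y[idx]);
      if (fy < std::exp(-0.5 * xcand * xcand)) return sign * xcand;
    }
  }
};

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes/weights on [-1, 1], Newton iteration; cached per n.

void gauleg(int n, std::vector<double>& x, std::vector<double>& w) {
  x.assign(n, 0.0); w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double zz = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1 = 2.0, pp = 0.0;
    while (std::fabs(zz - z1) > 1e-14) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * zz * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (zz * p1 - p2) / (zz * zz - 1.0);
      z1 = zz;
      zz = z1 - p1 / pp;
    }
    x[i] = -zz; x[n - 1 - i] = zz;
    w[i] = 2.0 / ((1.0 - zz * zz) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

const std::vector<double>* gl_nodes(int n, bool weights) {
  static std::vector<double> xs, ws;
  static int cached_n = -1;
  if (n != cached_n) { gauleg(n, xs, ws); cached_n = n; }
  return weights ? &ws : &xs;
}

// ---------------------------------------------------------------------------
// Density of first passage through the LOWER boundary for a unit-boundary
// (a=1), zero-drift process started at relative position z, at scaled time
// tau = t / a^2.  Two-regime series with the standard term-count switching
// rule controlled by eps (truncation tolerance).

double f0_lower(double tau, double z, double eps) {
  if (tau <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f;
  if (ks < kl) {                       // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double wk = z + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * tau));
    }
    f = s / std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {                             // large-time expansion
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * z);
    }
    f = M_PI * s;
  }
  return f > 0.0 ? f : 0.0;
}

// Lower-boundary density at decision time td for drift v, boundary a,
// relative start z.  sv > 0 is marginalised analytically (normal mixing of
// the drift multiplies the zero-drift kernel by a closed-form factor).
inline double wfpt_lower(double td, double v, double a, double z,
                         double sv, double eps) {
  if (td <= 0.0) return 0.0;
  double base = f0_lower(td / (a * a), z, eps) / (a * a);
  if (base <= 0.0) return 0.0;
  double A = a * z;
  double drift;
  if (sv > 0.0) {
    double s2t = 1.0 + sv * sv * td;
    drift = std::exp((A * A * sv * sv - 2.0 * v * A - v * v * td) / (2.0 * s2t)) /
            std::sqrt(s2t);
  } else {
    drift = std::exp(-v * A - v * v * td / 2.0);
  }
  return base * drift;
}

// Full density at observed RT for one boundary, marginalising uniform
// start-point range sz and non-decision-time range st by Gauss-Legendre
// quadrature (n_nodes per dimension); sv handled analytically above.
double wfpt_density_one(double rt, bool upper, double v, double a, double z,
                        double t0, double sv, double sz, double st,
                        double eps, int n_nodes) {
  // reflection: upper-boundary passage with (v, z) = lower with (-v, 1-z)
  double vv = upper ? -v : v;
  double zz = upper ? 1.0 - z : z;

  if (sz <= 0.0 && st <= 0.0) {
    return wfpt_lower(rt - t0, vv, a, zz, sv, eps);
  }
  const std::vector<double>& gx = *gl_nodes(n_nodes, false);
  const std::vector<double>& gw = *gl_nodes(n_nodes, true);

  double acc = 0.0;
  if (sz > 0.0 && st > 0.0) {
    for (int i = 0; i < n_nodes; ++i) {
      double ti = t0 + 0.5 * st * gx[i];
      double inner = 0.0;
      for (int j = 0; j < n_nodes; ++j) {
        double zj = zz + 0.5 * sz * gx[j];
        inner += gw[j] * wfpt_lower(rt - ti, vv, a, zj, sv, eps);
      }
      acc += gw[i] * inner / 2.0;
    }
    acc /= 2.0;
  } else if (sz > 0.0) {
    for (int j = 0; j < n_nodes; ++j) {
      double zj = zz + 0.5 * sz * gx[j];
      acc += gw[j] * wfpt_lower(rt - t0, vv, a, zj, sv, eps);
    }
    acc /= 2.0;
  } else {
    for (int i = 0; i < n_nodes; ++i) {
      double ti = t0 + 0.5 * st * gx[i];
      acc += gw[i] * wfpt_lower(rt - ti, vv, a, zz, sv, eps);
    }
    acc /= 2.0;
  }
  return acc > 0.0 ? acc : 0.0;
}

inline double recyc(const NumericVector& v, R_xlen_t i) {
  return v.size() == 1 ? v[0] : v[i];
}

} // anonymous namespace

// ---------------------------------------------------------------------------
// Exported interface

// [[Rcpp::export(name = ".wfpt_pdf_cpp")]]
NumericVector wfpt_pdf_cpp(NumericVector rt, IntegerVector upper,
                           NumericVector v, NumericVector a,
                           double z, double t0, double sv, double sz,
                           double st, double eps, int n_nodes) {
  R_xlen_t n = rt.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = wfpt_density_one(rt[i], upper[i] != 0, recyc(v, i), recyc(a, i),
                              z, t0, sv, sz, st, eps, n_nodes);
  }
  return out;
}

// [[Rcpp::export(name = ".wfpt_loglik_cpp")]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper,
                       NumericVector v, NumericVector a,
                       double z, double t0, double sv, double sz,
                       double st, double eps, int n_nodes) {
  R_xlen_t n = rt.size();
  double ll = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = wfpt_density_one(rt[i], upper[i] != 0, recyc(v, i), recyc(a, i),
                                z, t0, sv, sz, st, eps, n_nodes);
    if (!(d > 0.0)) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Probability of absorption at the upper boundary (no inter-trial
// variability): (1 - exp(-2 v a z)) / (1 - exp(-2 v a)); z for v = 0.
// [[Rcpp::export(name = ".choice_prob_cpp")]]
NumericVector choice_prob_cpp(NumericVector v, NumericVector a, NumericVector z) {
  R_xlen_t n = std::max(v.size(), std::max(a.size(), z.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double vi = recyc(v, i), ai = recyc(a, i), zi = recyc(z, i);
    double b = -2.0 * vi * ai;          // exponent scale
    double p;
    if (std::fabs(b) < 1e-9) {
      p = zi;
    } else if (b > 36.0) {              // strong negative drift
      p = std::exp(b * (zi - 1.0));
    } else if (b < -36.0) {             // strong positive drift
      p = -std::expm1(b * zi);
    } else {
      p = std::expm1(b * zi) / std::expm1(b);
    }
    out[i] = std::min(1.0, std::max(0.0, p));
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion with absorbing boundaries at 0
// and a. Per-trial drift in v; inter-trial variability draws: drift
// normal(v, sv), start uniform(z +/- sz/2), non-decision uniform(t0 +/- st/2).
// Paths exceeding max_t without absorption are resampled (count reported).
// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(NumericVector v, NumericVector a, double z, double t0,
                 double sv, double sz, double st, double dt, double max_t,
                 double seed) {
  R_xlen_t n = v.size();
  IntegerVector upper(n);
  NumericVector rt(n);
  long n_resampled = 0;
  Rng rng((uint64_t)seed);
  double sdt = std::sqrt(dt);
  long max_steps = (long)(max_t / dt);

  for (R_xlen_t i = 0; i < n; ++i) {
    double ai = recyc(a, i);
    // continuity correction for discrete monitoring of the continuous
    // barrier: shift each boundary inward by 0.5826 * sigma * sqrt(dt)
    double cc = 0.5826 * sdt;
    if (2.0 * cc >= ai) cc = 0.0;
    double hi = ai - cc, lo = cc;
    bool done = false;
    while (!done) {
      double vi = v[i] + (sv > 0.0 ? sv * rng.norm() : 0.0);
      double zi = z + (sz > 0.0 ? sz * (rng.unif() - 0.5) : 0.0);
      double ti = t0 + (st > 0.0 ? st * (rng.unif() - 0.5) : 0.0);
      double x = ai * zi;
      for (long s = 1; s <= max_steps; ++s) {
        x += vi * dt + sdt * rng.norm();
        if (x >= hi) { upper[i] = 1; rt[i] = s * dt + ti; done = true; break; }
        if (x <= lo) { upper[i] = 0; rt[i] = s * dt + ti; done = true; break; }
      }
      if (!done) ++n_resampled;
    }
  }
  return List::create(_["upper"] = upper, _["rt"] = rt,
                      _["n_resampled"] = (double)n_resampled);
}
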