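#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Counter-based deterministic RNG: splitmix64 stream + Box-Muller normals.
// Chosen over std:: distributions so trajectories are bit-identical across
// standard libraries and across kill/resume boundaries.

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

uint64_t mix3(uint64_t a, uint64_t b, uint64_t c) {
  SplitMix m(a);
  m.s ^= m.next() + b;
  m.s ^= m.next() + c;
  return m.next();
}

enum PotKind { FLAT = 0, HARMONIC = 1, DOUBLE_WELL = 2, TRIPLE_WELL = 3 };

// params layout:
//  harmonic:    k
//  double_well: barrier b, ky            U = b (x^2-1)^2 + ky/2 y^2
//  triple_well: depth b, sigma,          U = -b sum_i exp(-|r-c_i|^2/(2 s^2))
//               cx1,cy1,cx2,cy2,cx3,cy3
inline double pot_energy(int kind, const double* p, double x, double y) {
  switch (kind) {
  case FLAT: return 0.0;
  case HARMONIC: return 0.5 * p[0] * (x * x + y * y);
  case DOUBLE_WELL: {
    double a = x * x - 1.0;
    return p[0] * a * a + 0.5 * p[1] * y * y;
  }
  case TRIPLE_WELL: {
    double b = p[0], s2 = 2.0 * p[1] * p[1], u = 0.0;
    for (int i = 0; i < 3; ++i) {
      double dx = x - p[2 + 2 * i], dy = y - p[3 + 2 * i];
      u -= b * std::exp(-(dx * dx + dy * dy) / s2);
    }
    return u;
  }
  }
  return 0.0;
}

inline void pot_grad(int kind, const double* p, double x, double y,
                     double* gx, double* gy) {
  switch (kind) {
  case FLAT: *gx = 0.0; *gy = 0.0; return;
  case HARMONIC: *gx = p[0] * x; *gy = p[0] * y; return;
  case DOUBLE_WELL:
    *gx = 4.0 * p[0] * x * (x * x - 1.0);
    *gy = p[1] * y;
    return;
  case TRIPLE_WELL: {
    double b = p[0], s2 = 2.0 * p[1] * p[1];
    double ax = 0.0, ay = 0.0;
    for (int i = 0; i < 3; ++i) {
      double dx = x - p[2 + 2 * i], dy = y - p[3 + 2 * i];
      double e = b * std::exp(-(dx * dx + dy * dy) / s2) * (2.0 / s2);
      ax += e * dx;
      ay += e * dy;
    }
    *gx = ax; *gy = ay;
    return;
  }
  }
}

inline double reflect(double v, double lo, double hi) {
  // fold back into [lo, hi]; handles multiple crossings
  double span = hi - lo;
  if (v < lo - 2.0 * span || v > hi + 2.0 * span) {
    // large overshoot: modular fold into [lo, lo + 2 span) first
    double u = v - lo;
    u -= 2.0 * span * std::floor(u / (2.0 * span));
    v = lo + u;
  }
  while (v < lo || v > hi) {
    if (v < lo) v = 2.0 * lo - v;
    if (v > hi) v = 2.0 * hi - v;
    if (!std::isfinite(v)) break;
  }
  return v;
}

} // namespace

using namespace Rcpp;

// Propagate n walkers for n_steps of overdamped Langevin dynamics,
// saving every save_every steps. Each walker uses its own RNG stream
// seeded from (run_seed, lineage id, iteration) so sibling trajectories
// produced by resampling are statistically independent and any run is
// resumable at an iteration boundary without RNG state carry-over.
// [[Rcpp::export(name = ".propagate_walkers")]]
List propagate_walkers(NumericMatrix pos, IntegerVector lineage,
                       int iteration, double run_seed,
                       int n_steps, int save_every,
                       int pot_kind, NumericVector pot_params,
                       double dt, double D, double kT,
                       NumericVector domain, double noise_scale) {
  const int n = pos.nrow();
  if (pos.ncol() != 2) stop("walker positions must be 2-column");
  if (n_steps % save_every != 0)
    stop("n_steps must be a multiple of save_every");
  const int n_save = n_steps / save_every;
  const double drift = D * dt / kT;
  const double noise = noise_scale * std::sqrt(2.0 * D * dt);
  const double xlo = domain[0], xhi = domain[1];
  const double ylo = domain[2], yhi = domain[3];
  const double* pp = pot_params.begin();

  NumericVector frames(Dimension(n, n_save, 2));
  NumericMatrix fin(n, 2);

  for (int w = 0; w < n; ++w) {
    SplitMix rng(mix3((uint64_t)(int64_t)run_seed,
                      (uint64_t)(int64_t)lineage[w],
                      (uint64_t)(int64_t)iteration));
    double x = pos(w, 0), y = pos(w, 1);
    int si = 0;
    for (int t = 1; t <= n_steps; ++t) {
      double gx, gy;
      pot_grad(pot_kind, pp, x, y, &gx, &gy);
      x += -drift * gx + noise * rng.rnorm();
      y += -drift * gy + noise * rng.rnorm();
      if (!std::isfinite(x) || !std::isfinite(y))
        stop("non-finite coordinate for walker %d at step %d", w + 1, t);
      x = reflect(x, xlo, xhi);
      y = reflect(y, ylo, yhi);
      if (t % save_every == 0) {
        frames[w + n * si] = x;
        frames[w + n * (si + n_save)] = y;
        ++si;
      }
    }
    fin(w, 0) = x;
    fin(w, 1) = y;
  }
  return List::create(_["frames"] = frames, _["final"] = fin);
}

// Single long trajectory (the brute-force reference), subsampled.
// [[Rcpp::export(name = ".simulate_trajectory")]]
NumericMatrix simulate_trajectory(NumericVector start, double seed,
                                  double n_steps_d, int save_every,
                                  int pot_kind, NumericVector pot_params,
                                  double dt, double D, double kT,
                                  NumericVector domain, double noise_scale) {
  const long long n_steps = (long long)n_steps_d;
  const long long n_save = n_steps / save_every;
  const double drift = D * dt / kT;
  const double noise = noise_scale * std::sqrt(2.0 * D * dt);
  const double xlo = domain[0], xhi = domain[1];
  const double ylo = domain[2], yhi = domain[3];
  const double* pp = pot_params.begin();

  SplitMix rng(mix3((uint64_t)(int64_t)seed, 0x5EEDULL, 0xF00DULL));
  NumericMatrix out(n_save, 2);
  double x = start[0], y = start[1];
  long long si = 0;
  for (long long t = 1; t <= n_steps; ++t) {
    double gx, gy;
    pot_grad(pot_kind, pp, x, y, &gx, &gy);
    x += -drift * gx + noise * rng.rnorm();
    y += -drift * gy + noise * rng.rnorm();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("non-finite coordinate at step %lld", t);
    x = reflect(x, xlo, xhi);
    y = reflect(y, ylo, yhi);
    if (t % save_every == 0) {
      out(si, 0) = x;
      out(si, 1) = y;
      ++si;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".pot_energy_cpp")]]
NumericVector pot_energy_cpp(NumericMatrix pts, int pot_kind,
                             NumericVector pot_params) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pot_energy(pot_kind, pot_params.begin(), pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export(name = ".pot_grad_cpp")]]
NumericMatrix pot_grad_cpp(NumericMatrix pts, int pot_kind,
                           NumericVector pot_params) {
  const int n = pts.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double gx, gy;
    pot_grad(pot_kind, pot_params.begin(), pts(i, 0), pts(i, 1), &gx, &gy);
    out(i, 0) = gx;
    out(i, 1) = gy;
  }
  return out;
}
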