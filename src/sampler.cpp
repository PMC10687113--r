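// Simulated-annealing engine for the history-dependent sampler.
//
// Mirrors the R-side geometry exactly: a pseudo-chain of fixed-length bonds
// from the stationary anchor parameterized by a first-bond direction
// (alpha, beta), per-bond deflections delta in [0, delta_max] and torsions
// phi; the moving body's rotation is a free quaternion and its translation
// is derived from the chain end, so the linker is closed by construction.
// Penalties are evaluated by linear interpolation on the gridded working
// distributions (zero outside the measured support, i.e. maximal penalty A
// unless the restraint is flattened/inactive).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  double r0, dr, pmax;
  std::vector<double> p;
  bool active;
};

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 unit(Vec3 a) { double n = norm(a); return {a.x / n, a.y / n, a.z / n}; }

struct Quat {
  double w, x, y, z;
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
};

inline Quat qmul(const Quat& a, const Quat& b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

struct Mat3 {
  double m[9];
  Vec3 apply(Vec3 v) const {
    return {m[0] * v.x + m[1] * v.y + m[2] * v.z,
            m[3] * v.x + m[4] * v.y + m[5] * v.z,
            m[6] * v.x + m[7] * v.y + m[8] * v.z};
  }
};

inline Mat3 quat_to_mat(const Quat& q) {
  Mat3 R;
  R.m[0] = 1 - 2 * (q.y * q.y + q.z * q.z);
  R.m[1] = 2 * (q.x * q.y - q.w * q.z);
  R.m[2] = 2 * (q.x * q.z + q.w * q.y);
  R.m[3] = 2 * (q.x * q.y + q.w * q.z);
  R.m[4] = 1 - 2 * (q.x * q.x + q.z * q.z);
  R.m[5] = 2 * (q.y * q.z - q.w * q.x);
  R.m[6] = 2 * (q.x * q.z - q.w * q.y);
  R.m[7] = 2 * (q.y * q.z + q.w * q.x);
  R.m[8] = 1 - 2 * (q.x * q.x + q.y * q.y);
  return R;
}

// Deterministic perpendicular frame; must match R's perp_frame().
inline void perp_frame(Vec3 d, Vec3& e1, Vec3& e2) {
  double ax = std::fabs(d.x), ay = std::fabs(d.y), az = std::fabs(d.z);
  Vec3 e;
  if (ax <= ay && ax <= az) e = {1, 0, 0};
  else if (ay <= az) e = {0, 1, 0};
  else e = {0, 0, 1};
  e1 = unit(e - dot(e, d) * d);
  e2 = cross(d, e1);
}

inline Vec3 deflect(Vec3 d, double delta, double phi) {
  Vec3 e1, e2;
  perp_frame(d, e1, e2);
  return std::cos(delta) * d +
         std::sin(delta) * (std::cos(phi) * e1 + std::sin(phi) * e2);
}

inline double grid_eval(const Grid& g, double r) {
  double x = (r - g.r0) / g.dr;
  int n = (int)g.p.size();
  if (x < 0 || x > n - 1) return 0.0;
  int i = (int)std::floor(x);
  if (i >= n - 1) return g.p[n - 1];
  double f = x - i;
  return g.p[i] * (1 - f) + g.p[i + 1] * f;
}

// splitmix64 -> mt19937 seeding for well-decorrelated per-structure streams.
inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Small deterministic RNG (xorshift-based) so trajectories are reproducible
// independent of the C++ standard library's distribution implementations.
struct Rng {
  std::uint64_t s;
  explicit Rng(std::uint64_t seed) : s(splitmix64(seed ? seed : 1)) {}
  double uniform() {  // (0, 1)
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return ((s >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {  // Box-Muller, one value per call (second discarded)
    double u1 = uniform(), u2 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// floor-based modulo (avoids std::fmod, whose symbol version in recent
// glibc sysroots is newer than some host loaders provide)
inline double fmod_floor(double x, double y) {
  return x - y * std::floor(x / y);
}

inline double wrap_angle(double x) {
  double y = fmod_floor(x + M_PI, 2 * M_PI) - M_PI;
  if (y <= -M_PI) y = M_PI;
  return y;
}

inline double reflect_into(double x, double lo, double hi) {
  double range = hi - lo;
  if (range <= 0) return lo;
  double y = fmod_floor(x - lo, 2 * range);
  if (y > range) y = 2 * range - y;
  return lo + y;
}

struct System {
  std::vector<Vec3> stat_xyz, mov_xyz, label_xyz;
  std::vector<double> stat_radii, mov_radii;
  std::vector<int> label_body, pair_a, pair_b;
  std::vector<Grid> grids;
  Vec3 anchor_s, anchor_m;
  int nb;
  double bond_length, delta_max, A, c, k_steric, k_oos;
};

struct Params {
  Quat q;
  double alpha, beta;
  std::vector<double> delta, phi;
};

struct EvalResult {
  double target;
  std::vector<double> dist;
};

void evaluate(const System& sys, const Params& pr, EvalResult& out) {
  // chain from stationary anchor
  Vec3 d = {std::sin(pr.alpha) * std::cos(pr.beta),
            std::sin(pr.alpha) * std::sin(pr.beta), std::cos(pr.alpha)};
  Vec3 p = sys.anchor_s + sys.bond_length * d;
  for (int i = 1; i < sys.nb; ++i) {
    d = deflect(d, pr.delta[i - 1], pr.phi[i - 1]);
    p = p + sys.bond_length * d;
  }
  Mat3 R = quat_to_mat(pr.q);
  Vec3 t = p - R.apply(sys.anchor_m);

  // label world positions and restraint penalties
  size_t nl = sys.label_xyz.size();
  std::vector<Vec3> lw(nl);
  for (size_t i = 0; i < nl; ++i) {
    lw[i] = sys.label_body[i] ? R.apply(sys.label_xyz[i]) + t : sys.label_xyz[i];
  }
  double target = 0.0;
  for (size_t i = 0; i < sys.pair_a.size(); ++i) {
    Vec3 dv = lw[sys.pair_a[i]] - lw[sys.pair_b[i]];
    double r = norm(dv);
    out.dist[i] = r;
    const Grid& g = sys.grids[i];
    if (g.active) {
      double lo = g.r0, hi = g.r0 + g.dr * (g.p.size() - 1);
      if (r < lo || r > hi) {
        // outside the measured support: maximal penalty plus a quadratic
        // out-of-range term restoring towards observed distances
        double excess = (r < lo) ? lo - r : r - hi;
        target += sys.A + sys.k_oos * excess * excess;
      } else {
        double P = grid_eval(g, r);
        double s = 1.0 - P / (g.pmax * sys.c);
        if (s > 0) target += sys.A * s;
      }
    }
  }

  // soft-sphere steric overlap, stationary x moving
  for (size_t j = 0; j < sys.mov_xyz.size(); ++j) {
    Vec3 mj = R.apply(sys.mov_xyz[j]) + t;
    double rj = sys.mov_radii[j];
    for (size_t i = 0; i < sys.stat_xyz.size(); ++i) {
      Vec3 dv = sys.stat_xyz[i] - mj;
      double dmin = sys.stat_radii[i] + rj;
      double d2 = dot(dv, dv);
      if (d2 < dmin * dmin) {
        double ov = dmin - std::sqrt(d2);
        target += sys.k_steric * ov * ov;
      }
    }
  }
  out.target = target;
}

}  // namespace

// [[Rcpp::export]]
List run_structures_cpp(NumericMatrix stat_xyz, NumericMatrix mov_xyz,
                        NumericVector stat_radii, NumericVector mov_radii,
                        NumericVector anchor_s, NumericVector anchor_m,
                        int n_bonds, double bond_length, double delta_max,
                        IntegerVector label_body, NumericMatrix label_xyz,
                        IntegerVector pair_a, IntegerVector pair_b,
                        List grids, double A, double c, double k_steric,
                        double k_oos, int anneal_steps, double T_start,
                        double T_end,
                        double sig_rot, double sig_ang, double sig_delta,
                        IntegerVector seeds) {
  System sys;
  auto mat_to_vec = [](NumericMatrix m) {
    std::vector<Vec3> v(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) v[i] = {m(i, 0), m(i, 1), m(i, 2)};
    return v;
  };
  sys.stat_xyz = mat_to_vec(stat_xyz);
  sys.mov_xyz = mat_to_vec(mov_xyz);
  sys.label_xyz = mat_to_vec(label_xyz);
  sys.stat_radii = as<std::vector<double>>(stat_radii);
  sys.mov_radii = as<std::vector<double>>(mov_radii);
  sys.label_body = as<std::vector<int>>(label_body);
  sys.pair_a = as<std::vector<int>>(pair_a);
  sys.pair_b = as<std::vector<int>>(pair_b);
  sys.anchor_s = {anchor_s[0], anchor_s[1], anchor_s[2]};
  sys.anchor_m = {anchor_m[0], anchor_m[1], anchor_m[2]};
  sys.nb = n_bonds;
  sys.bond_length = bond_length;
  sys.delta_max = delta_max;
  sys.A = A;
  sys.c = c;
  sys.k_steric = k_steric;
  sys.k_oos = k_oos;
  for (int i = 0; i < grids.size(); ++i) {
    List g = grids[i];
    Grid gr;
    gr.r0 = as<double>(g["r0"]);
    gr.dr = as<double>(g["dr"]);
    gr.pmax = as<double>(g["pmax"]);
    gr.p = as<std::vector<double>>(g["p"]);
    gr.active = as<bool>(g["active"]) && gr.pmax > 0;
    sys.grids.push_back(gr);
  }

  int ns = seeds.size();
  int na = std::max(0, n_bonds - 1);
  int np = (int)sys.pair_a.size();
  NumericVector out_target(ns);
  NumericMatrix out_quat(ns, 4), out_delta(ns, std::max(1, na)),
      out_phi(ns, std::max(1, na)), out_dist(ns, std::max(1, np));
  NumericVector out_alpha(ns), out_beta(ns);

  double cool = (anneal_steps > 1)
                    ? std::pow(T_end / T_start, 1.0 / (anneal_steps - 1))
                    : 1.0;

  for (int s = 0; s < ns; ++s) {
    Rng rng((std::uint64_t)(std::uint32_t)seeds[s]);
    Params cur;
    cur.q = {rng.normal(), rng.normal(), rng.normal(), rng.normal()};
    cur.q.normalize();
    cur.alpha = std::acos(1.0 - 2.0 * rng.uniform());
    cur.beta = (2.0 * rng.uniform() - 1.0) * M_PI;
    cur.delta.resize(na);
    cur.phi.resize(na);
    for (int i = 0; i < na; ++i) {
      cur.delta[i] = rng.uniform() * delta_max;
      cur.phi[i] = (2.0 * rng.uniform() - 1.0) * M_PI;
    }

    EvalResult cur_ev, prop_ev, best_ev;
    cur_ev.dist.resize(np);
    prop_ev.dist.resize(np);
    best_ev.dist.resize(np);
    evaluate(sys, cur, cur_ev);
    Params best = cur;
    best_ev = cur_ev;

    double T = T_start;
    Params prop = cur;
    for (int step = 0; step < anneal_steps; ++step) {
      // propose: small rotation + jitter on all chain parameters
      prop = cur;
      Vec3 ax = {rng.normal(), rng.normal(), rng.normal()};
      double an = norm(ax);
      if (an > 1e-12) {
        ax = (1.0 / an) * ax;
        double ang = rng.normal() * sig_rot;
        Quat dq = {std::cos(ang / 2), std::sin(ang / 2) * ax.x,
                   std::sin(ang / 2) * ax.y, std::sin(ang / 2) * ax.z};
        prop.q = qmul(dq, cur.q);
        prop.q.normalize();
      }
      prop.alpha = reflect_into(cur.alpha + rng.normal() * sig_ang, 0.0, M_PI);
      prop.beta = wrap_angle(cur.beta + rng.normal() * sig_ang);
      for (int i = 0; i < na; ++i) {
        prop.delta[i] =
            reflect_into(cur.delta[i] + rng.normal() * sig_delta, 0.0, delta_max);
        prop.phi[i] = wrap_angle(cur.phi[i] + rng.normal() * sig_ang);
      }
      evaluate(sys, prop, prop_ev);
      double dE = prop_ev.target - cur_ev.target;
      if (dE <= 0 || rng.uniform() < std::exp(-dE / T)) {
        cur = prop;
        cur_ev = prop_ev;
        if (cur_ev.target < best_ev.target) {
          best = cur;
          best_ev = cur_ev;
        }
      }
      T *= cool;
    }

    out_target[s] = best_ev.target;
    out_quat(s, 0) = best.q.w;
    out_quat(s, 1) = best.q.x;
    out_quat(s, 2) = best.q.y;
    out_quat(s, 3) = best.q.z;
    out_alpha[s] = best.alpha;
    out_beta[s] = best.beta;
    for (int i = 0; i < na; ++i) {
      out_delta(s, i) = best.delta[i];
      out_phi(s, i) = best.phi[i];
    }
    for (int i = 0; i < np; ++i) out_dist(s, i) = best_ev.dist[i];
  }

  return List::create(
      Named("target") = out_target, Named("quat") = out_quat,
      Named("alpha") = out_alpha, Named("beta") = out_beta,
      Named("delta") = out_delta, Named("phi") = out_phi,
      Named("dist") = out_dist);
}
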