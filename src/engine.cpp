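// Overdamped Brownian-dynamics engine for the two-particle Syntaxin-1A
// dimer model on a disk-shaped membrane patch.
//
// Units: nm, ns, k_BT (k_BT == 1). Each molecule is a dimer: particle 1
// (anchor, radius r1) is restrained to the membrane plane z = 0 and carries
// the piecewise-harmonic clustering attraction; particle 2 (head, radius r2)
// is bonded to the anchor and interacts by soft-core repulsion only.
//
// Euler-Maruyama update per mobile particle:
//   dx = Dp * F * dt + sqrt(2 * Dp * dt) * xi,  xi ~ N(0,1) per coordinate.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64, with a ziggurat normal sampler.
// A private generator keeps runs bit-reproducible for a given integer seed
// independently of R's RNG state.

namespace bdrng {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang ziggurat for the standard normal (128 layers).
struct Ziggurat {
  uint64_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint64_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint64_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double sample(Xoshiro& rng) {
    for (;;) {
      uint64_t u = rng.next();
      int64_t hz = (int64_t)(int32_t)(uint32_t)(u & 0xffffffffULL);
      int iz = (int)((u >> 32) & 127);
      if ((uint64_t)std::llabs(hz) < kn[iz]) return hz * wn[iz];
      // slow path
      const double r = 3.442619855899;
      double x, y;
      if (iz == 0) {
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      // retry with fresh bits
    }
  }
};

}  // namespace bdrng

// ---------------------------------------------------------------------------
// Pair potential kernels. Each returns energy and writes dU/dd.

static inline double pot_attraction(double d, double r, double irad,
                                    double Ea, double* dU) {
  // piecewise-harmonic clustering potential between anchors; core stiffness
  // equals the well depth Ea.
  if (d >= irad) {
    *dU = 0.0;
    return 0.0;
  }
  double mid = 0.5 * (irad + r);
  if (d < r) {
    *dU = Ea * (d - r);
    return 0.5 * Ea * (d - r) * (d - r) - Ea;
  }
  double c = 2.0 * Ea / ((irad - r) * (irad - r));
  if (d < mid) {
    *dU = 2.0 * c * (d - r);
    return c * (d - r) * (d - r) - Ea;
  }
  *dU = -2.0 * c * (d - irad);
  return -c * (d - irad) * (d - irad);
}

static inline double pot_repulsion(double d, double rsum, double k,
                                   double* dU) {
  if (d >= rsum) {
    *dU = 0.0;
    return 0.0;
  }
  *dU = k * (d - rsum);
  return 0.5 * k * (d - rsum) * (d - rsum);
}

// ---------------------------------------------------------------------------
// Parameter bundle

struct Params {
  double r1, r2, Dp, dt, km, krep, kbond, kwall, R, ioff;
  double r11, r22, r12, i11, bond0;
  void derive() {
    r11 = 2.0 * r1;
    r22 = 2.0 * r2;
    r12 = r1 + r2;
    i11 = r11 + ioff;
    bond0 = r1 + r2;
  }
};

static Params read_params(const List& par) {
  Params p;
  p.r1 = as<double>(par["r1"]);
  p.r2 = as<double>(par["r2"]);
  p.Dp = as<double>(par["Dp"]);
  p.dt = as<double>(par["dt"]);
  p.km = as<double>(par["km"]);
  p.krep = as<double>(par["krep"]);
  p.kbond = as<double>(par["kbond"]);
  p.kwall = as<double>(par["kwall"]);
  p.R = as<double>(par["R"]);
  p.ioff = as<double>(par["ioff"]);
  p.derive();
  return p;
}

// ---------------------------------------------------------------------------
// Force evaluation over explicit pair lists. Positions are flat arrays
// x1[3*i + k] (anchors) and x2 (heads). Forces accumulated into f1/f2;
// returns total potential energy (pair + external terms).

struct PairLists {
  std::vector<int> aa;   // anchor-anchor (attraction), pairs (i,j) flattened
  std::vector<int> hh;   // head-head repulsion
  std::vector<int> ah;   // anchor(i)-head(j) repulsion, i != j (both orders)
};

static inline double dist3(const double* a, const double* b, double* dvec) {
  dvec[0] = a[0] - b[0];
  dvec[1] = a[1] - b[1];
  dvec[2] = a[2] - b[2];
  return std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                   dvec[2] * dvec[2]);
}

static double eval_forces(const std::vector<double>& x1,
                          const std::vector<double>& x2,
                          const std::vector<double>& Ea, const Params& p,
                          const PairLists& pl, std::vector<double>& f1,
                          std::vector<double>& f2) {
  int n = (int)Ea.size();
  std::fill(f1.begin(), f1.end(), 0.0);
  std::fill(f2.begin(), f2.end(), 0.0);
  double U = 0.0;
  double dv[3];

  // intra-molecular bond + membrane restraint + wall (anchors only)
  for (int i = 0; i < n; ++i) {
    const double* a = &x1[3 * i];
    const double* h = &x2[3 * i];
    double d = dist3(a, h, dv);
    if (d > 1e-12) {
      double dU = p.kbond * (d - p.bond0);
      U += 0.5 * p.kbond * (d - p.bond0) * (d - p.bond0);
      double s = -dU / d;
      for (int k = 0; k < 3; ++k) {
        f1[3 * i + k] += s * dv[k];
        f2[3 * i + k] -= s * dv[k];
      }
    }
    double z = a[2];
    U += 0.5 * p.km * z * z;
    f1[3 * i + 2] += -p.km * z;
    double rho = std::sqrt(a[0] * a[0] + a[1] * a[1]);
    if (rho > p.R && rho > 1e-12) {
      double dU = p.kwall * (rho - p.R);
      U += 0.5 * p.kwall * (rho - p.R) * (rho - p.R);
      double s = -dU / rho;
      f1[3 * i + 0] += s * a[0];
      f1[3 * i + 1] += s * a[1];
    }
  }

  // anchor-anchor clustering attraction
  const double c11 = p.i11 * p.i11, c22 = p.r22 * p.r22,
               c12 = p.r12 * p.r12;
  for (size_t q = 0; q < pl.aa.size(); q += 2) {
    int i = pl.aa[q], j = pl.aa[q + 1];
    const double* a = &x1[3 * i];
    const double* b = &x1[3 * j];
    dv[0] = a[0] - b[0]; dv[1] = a[1] - b[1]; dv[2] = a[2] - b[2];
    double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (d2 >= c11 || d2 < 1e-24) continue;
    double d = std::sqrt(d2);
    double Eij = Ea[i] > Ea[j] ? Ea[i] : Ea[j];
    double dU;
    U += pot_attraction(d, p.r11, p.i11, Eij, &dU);
    double s = -dU / d;
    for (int k = 0; k < 3; ++k) {
      f1[3 * i + k] += s * dv[k];
      f1[3 * j + k] -= s * dv[k];
    }
  }
  // head-head repulsion
  for (size_t q = 0; q < pl.hh.size(); q += 2) {
    int i = pl.hh[q], j = pl.hh[q + 1];
    const double* a = &x2[3 * i];
    const double* b = &x2[3 * j];
    dv[0] = a[0] - b[0]; dv[1] = a[1] - b[1]; dv[2] = a[2] - b[2];
    double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (d2 >= c22 || d2 < 1e-24) continue;
    double d = std::sqrt(d2);
    double dU;
    U += pot_repulsion(d, p.r22, p.krep, &dU);
    double s = -dU / d;
    for (int k = 0; k < 3; ++k) {
      f2[3 * i + k] += s * dv[k];
      f2[3 * j + k] -= s * dv[k];
    }
  }
  // anchor-head cross repulsion
  for (size_t q = 0; q < pl.ah.size(); q += 2) {
    int i = pl.ah[q], j = pl.ah[q + 1];  // anchor i vs head j
    const double* a = &x1[3 * i];
    const double* b = &x2[3 * j];
    dv[0] = a[0] - b[0]; dv[1] = a[1] - b[1]; dv[2] = a[2] - b[2];
    double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (d2 >= c12 || d2 < 1e-24) continue;
    double d = std::sqrt(d2);
    double dU;
    U += pot_repulsion(d, p.r12, p.krep, &dU);
    double s = -dU / d;
    for (int k = 0; k < 3; ++k) {
      f1[3 * i + k] += s * dv[k];
      f2[3 * j + k] -= s * dv[k];
    }
  }
  return U;
}

// Build all-pairs lists (every distinct pair, both cross orders).
static PairLists all_pairs(int n) {
  PairLists pl;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      pl.aa.push_back(i);
      pl.aa.push_back(j);
      pl.hh.push_back(i);
      pl.hh.push_back(j);
      pl.ah.push_back(i);
      pl.ah.push_back(j);
      pl.ah.push_back(j);
      pl.ah.push_back(i);
    }
  return pl;
}

// Verlet lists with an explicit skin; valid while no particle has moved
// more than skin/2 since the rebuild.
static void build_verlet(const std::vector<double>& x1,
                         const std::vector<double>& x2, const Params& p,
                         double skin, PairLists& pl) {
  int n = (int)(x1.size() / 3);
  pl.aa.clear();
  pl.hh.clear();
  pl.ah.clear();
  double c_aa = (p.i11 + skin) * (p.i11 + skin);
  double c_hh = (p.r22 + skin) * (p.r22 + skin);
  double c_ah = (p.r12 + skin) * (p.r12 + skin);
  for (int i = 0; i < n; ++i) {
    const double* a_i = &x1[3 * i];
    const double* h_i = &x2[3 * i];
    for (int j = i + 1; j < n; ++j) {
      const double* a_j = &x1[3 * j];
      const double* h_j = &x2[3 * j];
      double dx = a_i[0] - a_j[0], dy = a_i[1] - a_j[1],
             dz = a_i[2] - a_j[2];
      if (dx * dx + dy * dy + dz * dz < c_aa) {
        pl.aa.push_back(i);
        pl.aa.push_back(j);
      }
      dx = h_i[0] - h_j[0];
      dy = h_i[1] - h_j[1];
      dz = h_i[2] - h_j[2];
      if (dx * dx + dy * dy + dz * dz < c_hh) {
        pl.hh.push_back(i);
        pl.hh.push_back(j);
      }
      dx = a_i[0] - h_j[0];
      dy = a_i[1] - h_j[1];
      dz = a_i[2] - h_j[2];
      if (dx * dx + dy * dy + dz * dz < c_ah) {
        pl.ah.push_back(i);
        pl.ah.push_back(j);
      }
      dx = a_j[0] - h_i[0];
      dy = a_j[1] - h_i[1];
      dz = a_j[2] - h_i[2];
      if (dx * dx + dy * dy + dz * dz < c_ah) {
        pl.ah.push_back(j);
        pl.ah.push_back(i);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// All-pairs energy/forces, R-callable (reference path for tests and for
// single-configuration energy queries).

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(NumericMatrix pos1, NumericMatrix pos2, NumericVector Ea,
                List par) {
  int n = pos1.nrow();
  Params p = read_params(par);
  std::vector<double> x1(3 * n), x2(3 * n), f1(3 * n), f2(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      x1[3 * i + k] = pos1(i, k);
      x2[3 * i + k] = pos2(i, k);
    }
  std::vector<double> ea(Ea.begin(), Ea.end());
  PairLists pl = all_pairs(n);
  double U = eval_forces(x1, x2, ea, p, pl, f1, f2);
  NumericMatrix F1(n, 3), F2(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      F1(i, k) = f1[3 * i + k];
      F2(i, k) = f2[3 * i + k];
    }
  return List::create(_["energy"] = U, _["f1"] = F1, _["f2"] = F2);
}

// Same quantities through the Verlet-list path (exposed so tests can verify
// the neighbor-list forces match the all-pairs forces exactly).

// [[Rcpp::export(name = ".cpp_forces_verlet")]]
List cpp_forces_verlet(NumericMatrix pos1, NumericMatrix pos2,
                       NumericVector Ea, List par, double skin) {
  int n = pos1.nrow();
  Params p = read_params(par);
  std::vector<double> x1(3 * n), x2(3 * n), f1(3 * n), f2(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      x1[3 * i + k] = pos1(i, k);
      x2[3 * i + k] = pos2(i, k);
    }
  std::vector<double> ea(Ea.begin(), Ea.end());
  PairLists pl;
  build_verlet(x1, x2, p, skin, pl);
  double U = eval_forces(x1, x2, ea, p, pl, f1, f2);
  NumericMatrix F1(n, 3), F2(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      F1(i, k) = f1[3 * i + k];
      F2(i, k) = f2[3 * i + k];
    }
  return List::create(_["energy"] = U, _["f1"] = F1, _["f2"] = F2);
}

// ---------------------------------------------------------------------------
// Main integrator.
//
// Optional trackers:
//  * coverage: mark 2D lattice cells (edge `coverage_cell` nm, lattice
//    covering the bounding square of the disk) as visited when an anchor
//    center falls inside; early stop when the visited fraction of in-disk
//    cells reaches `coverage_stop`.
//  * seed tracking: every `seed_check_stride` steps compute the size of the
//    distance-cutoff cluster containing molecule `seed_index`; early stop
//    when it reaches `seed_target`.

struct UnionFind {
  std::vector<int> parent;
  void init(int n) {
    parent.resize(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[a] = b;
  }
};

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(NumericMatrix pos1, NumericMatrix pos2, LogicalVector mobile,
             NumericVector Ea, List par, double n_steps_d, int stride,
             double seed_d, bool record, double cluster_cutoff,
             double coverage_cell, double coverage_stop,
             int seed_index, int seed_target, int seed_check_stride) {
  const int n = pos1.nrow();
  const Params p = read_params(par);
  const long long n_steps = (long long)n_steps_d;
  bdrng::Xoshiro rng((uint64_t)seed_d);
  static bdrng::Ziggurat zigg;

  std::vector<double> x1(3 * n), x2(3 * n), f1(3 * n), f2(3 * n);
  std::vector<char> mob(n);
  for (int i = 0; i < n; ++i) {
    mob[i] = mobile[i] ? 1 : 0;
    for (int k = 0; k < 3; ++k) {
      x1[3 * i + k] = pos1(i, k);
      x2[3 * i + k] = pos2(i, k);
    }
  }
  std::vector<double> ea(Ea.begin(), Ea.end());

  const double skin = 2.0;
  const double half_skin2 = (skin / 2.0) * (skin / 2.0);
  PairLists pl;
  build_verlet(x1, x2, p, skin, pl);
  std::vector<double> ref1(x1), ref2(x2);

  const double sigma = std::sqrt(2.0 * p.Dp * p.dt);
  const double mobpref = p.Dp * p.dt;
  const double max_disp2 = p.r1 * p.r1;
  long long n_big_steps = 0, n_rebuilds = 0;

  // sampling storage
  long long n_frames = record ? (n_steps / stride + 1) : 0;
  NumericVector traj1(record ? (R_xlen_t)(3 * n * n_frames) : 0);
  NumericVector traj2(record ? (R_xlen_t)(3 * n * n_frames) : 0);
  NumericVector times(record ? (R_xlen_t)n_frames : 0);
  NumericVector energies(record ? (R_xlen_t)n_frames : 0);

  // coverage tracker
  bool do_cov = coverage_cell > 0.0;
  int ncell = 0, n_in_disk = 0;
  std::vector<char> visited;
  std::vector<char> in_disk;
  std::vector<long long> first_visit;
  long long n_visited = 0;
  double cov_org = 0.0;
  if (do_cov) {
    ncell = (int)std::ceil(2.0 * p.R / coverage_cell);
    cov_org = -0.5 * ncell * coverage_cell;  // lattice centered on axis
    visited.assign((size_t)ncell * ncell, 0);
    in_disk.assign((size_t)ncell * ncell, 0);
    first_visit.assign((size_t)ncell * ncell, -1);
    for (int cy = 0; cy < ncell; ++cy)
      for (int cx = 0; cx < ncell; ++cx) {
        double mx = cov_org + (cx + 0.5) * coverage_cell;
        double my = cov_org + (cy + 0.5) * coverage_cell;
        if (mx * mx + my * my <= p.R * p.R)
          in_disk[(size_t)cy * ncell + cx] = 1;
      }
    for (size_t c = 0; c < in_disk.size(); ++c) n_in_disk += in_disk[c];
  }
  auto mark_coverage = [&](long long step) {
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x1[3 * i] - cov_org) / coverage_cell);
      int cy = (int)std::floor((x1[3 * i + 1] - cov_org) / coverage_cell);
      if (cx < 0 || cy < 0 || cx >= ncell || cy >= ncell) continue;
      size_t c = (size_t)cy * ncell + cx;
      if (!visited[c] && in_disk[c]) {
        visited[c] = 1;
        first_visit[c] = step;
        ++n_visited;
      }
    }
  };

  // seed-cluster tracker
  bool do_seed = seed_index >= 0;
  UnionFind uf;
  std::vector<long long> seed_hit_step;  // first step at which size >= s
  int seed_max_size = 1;
  if (do_seed) seed_hit_step.assign(seed_target + 1, -1);
  auto seed_cluster_size = [&](void) {
    uf.init(n);
    double c2 = cluster_cutoff * cluster_cutoff;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x1[3 * i] - x1[3 * j];
        double dy = x1[3 * i + 1] - x1[3 * j + 1];
        double dz = x1[3 * i + 2] - x1[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < c2) uf.unite(i, j);
      }
    int root = uf.find(seed_index);
    int sz = 0;
    for (int i = 0; i < n; ++i)
      if (uf.find(i) == root) ++sz;
    return sz;
  };

  long long frame = 0;
  auto snapshot = [&](long long step, double U) {
    if (!record) return;
    R_xlen_t off = (R_xlen_t)(3 * n) * frame;
    for (int q = 0; q < 3 * n; ++q) {
      traj1[off + q] = x1[q];
      traj2[off + q] = x2[q];
    }
    times[frame] = step * p.dt;
    energies[frame] = U;
    ++frame;
  };

  double U = eval_forces(x1, x2, ea, p, pl, f1, f2);
  snapshot(0, U);
  if (do_cov) mark_coverage(0);
  if (do_seed) {
    int sz = seed_cluster_size();
    for (int s = 1; s <= sz && s <= seed_target; ++s)
      if (seed_hit_step[s] < 0) seed_hit_step[s] = 0;
    seed_max_size = sz;
  }

  long long stop_step = -1;
  for (long long step = 1; step <= n_steps; ++step) {
    // displace
    double maxmove2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      for (int k = 0; k < 3; ++k) {
        double d1 = mobpref * f1[3 * i + k] + sigma * zigg.sample(rng);
        double d2 = mobpref * f2[3 * i + k] + sigma * zigg.sample(rng);
        x1[3 * i + k] += d1;
        x2[3 * i + k] += d2;
        if (d1 * d1 > maxmove2) maxmove2 = d1 * d1;
        if (d2 * d2 > maxmove2) maxmove2 = d2 * d2;
      }
    }
    if (maxmove2 > max_disp2) ++n_big_steps;

    // Verlet validity: rebuild if any particle drifted > skin/2
    double drift2 = 0.0;
    for (int q = 0; q < 3 * n; q += 3) {
      double dx = x1[q] - ref1[q], dy = x1[q + 1] - ref1[q + 1],
             dz = x1[q + 2] - ref1[q + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > drift2) drift2 = d2;
      dx = x2[q] - ref2[q];
      dy = x2[q + 1] - ref2[q + 1];
      dz = x2[q + 2] - ref2[q + 2];
      d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > drift2) drift2 = d2;
    }
    if (drift2 > half_skin2) {
      build_verlet(x1, x2, p, skin, pl);
      ref1 = x1;
      ref2 = x2;
      ++n_rebuilds;
    }

    U = eval_forces(x1, x2, ea, p, pl, f1, f2);

    if (do_cov) mark_coverage(step);
    if (record && step % stride == 0) snapshot(step, U);

    if (do_seed && step % seed_check_stride == 0) {
      int sz = seed_cluster_size();
      if (sz > seed_max_size) {
        for (int s = seed_max_size + 1; s <= sz && s <= seed_target; ++s)
          if (seed_hit_step[s] < 0) seed_hit_step[s] = step;
        seed_max_size = sz;
      }
      if (sz >= seed_target) {
        stop_step = step;
        break;
      }
    }
    if (do_cov && coverage_stop > 0 &&
        (double)n_visited >= coverage_stop * n_in_disk) {
      stop_step = step;
      break;
    }
    if (step % 1000000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out1(n, 3), out2(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      out1(i, k) = x1[3 * i + k];
      out2(i, k) = x2[3 * i + k];
    }

  List res = List::create(
      _["pos1"] = out1, _["pos2"] = out2,
      _["n_big_steps"] = (double)n_big_steps,
      _["n_rebuilds"] = (double)n_rebuilds,
      _["stop_step"] = (double)stop_step);
  if (record) {
    traj1.attr("dim") = IntegerVector::create(3, n, (int)n_frames);
    traj2.attr("dim") = IntegerVector::create(3, n, (int)n_frames);
    // frames actually written may be fewer on early stop (see n_frames)
    res["traj1"] = traj1;
    res["traj2"] = traj2;
    res["times"] = times;
    res["energies"] = energies;
    res["n_frames"] = (double)frame;
  }
  if (do_cov) {
    NumericVector fv((R_xlen_t)first_visit.size());
    LogicalVector id((R_xlen_t)in_disk.size());
    for (size_t c = 0; c < first_visit.size(); ++c) {
      fv[c] = (double)first_visit[c];
      id[c] = in_disk[c] != 0;
    }
    fv.attr("dim") = IntegerVector::create(ncell, ncell);
    id.attr("dim") = IntegerVector::create(ncell, ncell);
    res["first_visit_step"] = fv;
    res["cell_in_disk"] = id;
    res["n_cells_in_disk"] = n_in_disk;
  }
  if (do_seed) {
    NumericVector hs((R_xlen_t)seed_hit_step.size() - 1);
    for (int s = 1; s <= seed_target; ++s) hs[s - 1] = (double)seed_hit_step[s];
    res["seed_hit_step"] = hs;
    res["seed_max_size"] = seed_max_size;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Standard-normal sampler exposed for distributional tests of the ziggurat.

// [[Rcpp::export(name = ".cpp_rnorm")]]
NumericVector cpp_rnorm(int n, double seed_d) {
  bdrng::Xoshiro rng((uint64_t)seed_d);
  static bdrng::Ziggurat zigg;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zigg.sample(rng);
  return out;
}

// ---------------------------------------------------------------------------
// Per-frame cluster labels by anchor-distance connected components.
// traj1 has dim (3, n, F). Returns an n x F integer matrix of cluster ids
// (1-based, renumbered in order of first member).

// [[Rcpp::export(name = ".cpp_cluster_frames")]]
IntegerMatrix cpp_cluster_frames(NumericVector traj1, double cutoff) {
  IntegerVector dims = traj1.attr("dim");
  int n = dims[1], F = dims[2];
  IntegerMatrix labels(n, F);
  UnionFind uf;
  double c2 = cutoff * cutoff;
  std::vector<int> remap(n);
  for (int f = 0; f < F; ++f) {
    const double* fr = &traj1[(R_xlen_t)3 * n * f];
    uf.init(n);
    for (int i = 0; i < n; ++i) {
      const double* a = fr + 3 * i;
      for (int j = i + 1; j < n; ++j) {
        const double* b = fr + 3 * j;
        double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
        if (dx * dx + dy * dy + dz * dz < c2) uf.unite(i, j);
      }
    }
    std::fill(remap.begin(), remap.end(), 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int r = uf.find(i);
      if (remap[r] == 0) remap[r] = ++next;
      labels(i, f) = remap[r];
    }
  }
  return labels;
}

// Neighbor counts: anchors within `radius` of each anchor, per frame.

// [[Rcpp::export(name = ".cpp_neighbor_counts")]]
IntegerMatrix cpp_neighbor_counts(NumericVector traj1, double radius) {
  IntegerVector dims = traj1.attr("dim");
  int n = dims[1], F = dims[2];
  IntegerMatrix counts(n, F);
  double c2 = radius * radius;
  for (int f = 0; f < F; ++f) {
    const double* fr = &traj1[(R_xlen_t)3 * n * f];
    for (int i = 0; i < n; ++i) {
      const double* a = fr + 3 * i;
      for (int j = i + 1; j < n; ++j) {
        const double* b = fr + 3 * j;
        double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
        if (dx * dx + dy * dy + dz * dz < c2) {
          ++counts(i, f);
          ++counts(j, f);
        }
      }
    }
  }
  return counts;
}
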