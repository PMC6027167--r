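// DPD integration core: soft conservative repulsion, pairwise
// dissipative/random thermostat, harmonic bonds, modified velocity-Verlet.
// All quantities in reduced units (lengths in r_c, energies in kT, mass 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based pair noise: theta_ij for a given (seed, step, i, j) with
// i < j enforced by the caller, so theta_ij == theta_ji exactly and runs
// are reproducible under any evaluation order. Uniform variate scaled to
// unit variance (the standard DPD choice; only the first two moments of the
// noise matter for the fluctuation-dissipation balance).
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double pair_noise(uint64_t seed, uint64_t step,
                                uint32_t i, uint32_t j) {
  uint64_t key = (static_cast<uint64_t>(i) << 32) | static_cast<uint64_t>(j);
  uint64_t h = splitmix64(seed ^ splitmix64(step + 0x632BE59BD9B4E019ULL) ^
                          splitmix64(key));
  double u = (h >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
  return 1.7320508075688772 * (2.0 * u - 1.0);        // variance exactly 1
}

// [[Rcpp::export]]
double cpp_pair_noise(double seed, double step, int i, int j) {
  uint32_t a = static_cast<uint32_t>(i < j ? i : j);
  uint32_t b = static_cast<uint32_t>(i < j ? j : i);
  return pair_noise(static_cast<uint64_t>(seed),
                    static_cast<uint64_t>(step), a, b);
}

// ---------------------------------------------------------------------------
// Simulation workspace
// ---------------------------------------------------------------------------
struct DpdSystem {
  int n;
  std::vector<double> x, v, f;   // 3N, x wrapped into [0, L)
  std::vector<int> img;          // 3N periodic image counters
  std::vector<int> type;         // 0-based bead type
  std::vector<int> bond_i, bond_j;
  double box[3];
  double rc, rc2;
  double gamma, sigma, lam, dt, inv_sqrt_dt;
  double bond_k, bond_r0;
  double force_cap;              // <= 0: uncapped
  uint64_t seed;
  const double* aij;             // ntypes x ntypes, column-major (symmetric)
  int ntypes;

  // cell list (counting sort into contiguous per-cell ranges; beads are
  // permuted into scratch arrays for cache-friendly pair traversal)
  int nc[3];
  bool use_cells;
  std::vector<int> head, nxt;           // linked list (neighbor enumeration)
  std::vector<int> cellv, cnt, permv, ids, nbr;
  std::vector<double> xs, vs, fs;

  void setup_cells() {
    for (int d = 0; d < 3; ++d) {
      nc[d] = static_cast<int>(std::floor(box[d] / rc));
      if (nc[d] < 1) nc[d] = 1;
    }
    use_cells = (nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3);
    if (use_cells) {
      size_t ncell = static_cast<size_t>(nc[0]) * nc[1] * nc[2];
      head.assign(ncell, -1);
      nxt.assign(n, -1);
      cellv.resize(n);
      cnt.resize(ncell + 1);
      permv.resize(n);
      ids.resize(n);
      xs.resize(3 * n);
      vs.resize(3 * n);
      fs.resize(3 * n);
      // precomputed half stencil of neighbouring cell indices
      static const int st[13][3] = {
        {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
        {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
        {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
        {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
      nbr.resize(ncell * 13);
      for (int cz = 0; cz < nc[2]; ++cz)
        for (int cy = 0; cy < nc[1]; ++cy)
          for (int cx = 0; cx < nc[0]; ++cx) {
            size_t c = (static_cast<size_t>(cz) * nc[1] + cy) * nc[0] + cx;
            for (int s = 0; s < 13; ++s) {
              int ox = (cx + st[s][0] + nc[0]) % nc[0];
              int oy = (cy + st[s][1] + nc[1]) % nc[1];
              int oz = (cz + st[s][2] + nc[2]) % nc[2];
              nbr[c * 13 + s] =
                (static_cast<size_t>(oz) * nc[1] + oy) * nc[0] + ox;
            }
          }
    }
  }

  inline int cell_of(int i) const {
    int cx = static_cast<int>(x[3 * i] / box[0] * nc[0]);
    int cy = static_cast<int>(x[3 * i + 1] / box[1] * nc[1]);
    int cz = static_cast<int>(x[3 * i + 2] / box[2] * nc[2]);
    if (cx >= nc[0]) cx = nc[0] - 1;
    if (cy >= nc[1]) cy = nc[1] - 1;
    if (cz >= nc[2]) cz = nc[2] - 1;
    return (cz * nc[1] + cy) * nc[0] + cx;
  }

  void bin_particles() {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(i);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline void min_image(double& dx, double& dy, double& dz) const {
    if (dx > 0.5 * box[0]) dx -= box[0]; else if (dx < -0.5 * box[0]) dx += box[0];
    if (dy > 0.5 * box[1]) dy -= box[1]; else if (dy < -0.5 * box[1]) dy += box[1];
    if (dz > 0.5 * box[2]) dz -= box[2]; else if (dz < -0.5 * box[2]) dz += box[2];
  }

  // non-bonded force between i and j for force evaluation counter `step`
  inline void pair_interact(int i, int j, uint64_t step) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double r = std::sqrt(r2);
    if (r < 1e-12) return;  // degenerate direction: zero force by convention
    double inv_r = 1.0 / r;
    double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
    double w = 1.0 - r / rc;

    double a = aij[type[i] + ntypes * type[j]];
    double fmag = a * w;  // conservative

    double dvx = v[3 * i] - v[3 * j];
    double dvy = v[3 * i + 1] - v[3 * j + 1];
    double dvz = v[3 * i + 2] - v[3 * j + 2];
    double rv = ex * dvx + ey * dvy + ez * dvz;
    fmag -= gamma * w * w * rv;  // dissipative

    uint32_t a_id = static_cast<uint32_t>(i < j ? i : j);
    uint32_t b_id = static_cast<uint32_t>(i < j ? j : i);
    double theta = pair_noise(seed, step, a_id, b_id);
    fmag += sigma * w * theta * inv_sqrt_dt;  // random

    f[3 * i] += fmag * ex;  f[3 * j] -= fmag * ex;
    f[3 * i + 1] += fmag * ey;  f[3 * j + 1] -= fmag * ey;
    f[3 * i + 2] += fmag * ez;  f[3 * j + 2] -= fmag * ez;
  }

  // pair force in the permuted (cell-sorted) arrays; a, b are sorted slots
  inline void pair_sorted(int a, int b, uint64_t step) {
    double dx = xs[3 * a] - xs[3 * b];
    double dy = xs[3 * a + 1] - xs[3 * b + 1];
    double dz = xs[3 * a + 2] - xs[3 * b + 2];
    min_image(dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double r = std::sqrt(r2);
    if (r < 1e-12) return;
    double inv_r = 1.0 / r;
    double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
    double w = 1.0 - r / rc;
    int i = ids[a], j = ids[b];
    double fmag = aij[type[i] + ntypes * type[j]] * w;
    double dvx = vs[3 * a] - vs[3 * b];
    double dvy = vs[3 * a + 1] - vs[3 * b + 1];
    double dvz = vs[3 * a + 2] - vs[3 * b + 2];
    fmag -= gamma * w * w * (ex * dvx + ey * dvy + ez * dvz);
    uint32_t lo = static_cast<uint32_t>(i < j ? i : j);
    uint32_t hi = static_cast<uint32_t>(i < j ? j : i);
    fmag += sigma * w * pair_noise(seed, step, lo, hi) * inv_sqrt_dt;
    fs[3 * a] += fmag * ex;  fs[3 * b] -= fmag * ex;
    fs[3 * a + 1] += fmag * ey;  fs[3 * b + 1] -= fmag * ey;
    fs[3 * a + 2] += fmag * ez;  fs[3 * b + 2] -= fmag * ez;
  }

  void compute_forces(uint64_t step) {
    std::fill(f.begin(), f.end(), 0.0);
    if (use_cells) {
      size_t ncell = head.size();
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < n; ++i) {
        cellv[i] = cell_of(i);
        ++cnt[cellv[i] + 1];
      }
      for (size_t c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
      {
        std::vector<int> fill(cnt.begin(), cnt.end() - 1);
        for (int i = 0; i < n; ++i) permv[fill[cellv[i]]++] = i;
      }
      for (int k = 0; k < n; ++k) {
        int i = permv[k];
        ids[k] = i;
        xs[3 * k] = x[3 * i]; xs[3 * k + 1] = x[3 * i + 1];
        xs[3 * k + 2] = x[3 * i + 2];
        vs[3 * k] = v[3 * i]; vs[3 * k + 1] = v[3 * i + 1];
        vs[3 * k + 2] = v[3 * i + 2];
      }
      std::fill(fs.begin(), fs.end(), 0.0);
      for (size_t c = 0; c < ncell; ++c) {
        int s0 = cnt[c], s1 = cnt[c + 1];
        for (int a = s0; a < s1; ++a)
          for (int b = a + 1; b < s1; ++b) pair_sorted(a, b, step);
        for (int s = 0; s < 13; ++s) {
          size_t c2 = nbr[c * 13 + s];
          int t0 = cnt[c2], t1 = cnt[c2 + 1];
          for (int a = s0; a < s1; ++a)
            for (int b = t0; b < t1; ++b) pair_sorted(a, b, step);
        }
      }
      for (int k = 0; k < n; ++k) {
        int i = permv[k];
        f[3 * i] = fs[3 * k];
        f[3 * i + 1] = fs[3 * k + 1];
        f[3 * i + 2] = fs[3 * k + 2];
      }
    } else {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j)
          pair_interact(i, j, step);
    }
    // harmonic bonds
    for (size_t k = 0; k < bond_i.size(); ++k) {
      int i = bond_i[k], j = bond_j[k];
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      min_image(dx, dy, dz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fmag = -bond_k * (r - bond_r0) / r;
      f[3 * i] += fmag * dx;  f[3 * j] -= fmag * dx;
      f[3 * i + 1] += fmag * dy;  f[3 * j + 1] -= fmag * dy;
      f[3 * i + 2] += fmag * dz;  f[3 * j + 2] -= fmag * dz;
    }
    if (force_cap > 0.0) {
      for (int i = 0; i < n; ++i) {
        double fm = std::sqrt(f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                              f[3 * i + 2] * f[3 * i + 2]);
        if (fm > force_cap) {
          double s = force_cap / fm;
          f[3 * i] *= s; f[3 * i + 1] *= s; f[3 * i + 2] *= s;
        }
      }
    }
  }

  void wrap(int i) {
    for (int d = 0; d < 3; ++d) {
      double& xi = x[3 * i + d];
      while (xi >= box[d]) { xi -= box[d]; img[3 * i + d] += 1; }
      while (xi < 0.0) { xi += box[d]; img[3 * i + d] -= 1; }
    }
  }

  double kinetic_temperature() const {
    if (n < 2) return 0.0;
    double cm[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) cm[d] += v[3 * i + d];
    for (int d = 0; d < 3; ++d) cm[d] /= n;
    double sum = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double dv = v[3 * i + d] - cm[d];
        sum += dv * dv;
      }
    return sum / (3.0 * (n - 1));
  }
};

static void check_finite(const DpdSystem& S, int step) {
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d)
      if (!std::isfinite(S.x[3 * i + d]) || !std::isfinite(S.v[3 * i + d]))
        stop("non-finite coordinate/velocity at step %d, bead %d", step, i + 1);
}

// ---------------------------------------------------------------------------
// Exported driver. Advances `n_steps` steps of the modified velocity-Verlet
// (prediction factor lambda) from global step counter `step0`. If `f0` has
// nrow == N it is taken as the force array of the entry state (exact
// checkpoint continuation); otherwise forces are evaluated at entry.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_dpd(NumericMatrix pos, NumericMatrix vel, IntegerMatrix images,
                 IntegerVector types, NumericMatrix aij, IntegerMatrix bonds,
                 double bond_k, double bond_r0, NumericVector box, double rc,
                 double gamma, double sigma, double lambda, double dt,
                 int n_steps, int step0, double seed, int snapshot_every,
                 int thermo_every, double force_cap, NumericMatrix f0) {
  int n = pos.nrow();
  DpdSystem S;
  S.n = n;
  S.x.resize(3 * n); S.v.resize(3 * n); S.f.assign(3 * n, 0.0);
  S.img.resize(3 * n);
  S.type.resize(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      S.x[3 * i + d] = pos(i, d);
      S.v[3 * i + d] = vel(i, d);
      S.img[3 * i + d] = images(i, d);
    }
    S.type[i] = types[i];
  }
  for (int k = 0; k < bonds.nrow(); ++k) {
    S.bond_i.push_back(bonds(k, 0));
    S.bond_j.push_back(bonds(k, 1));
  }
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.rc = rc; S.rc2 = rc * rc;
  S.gamma = gamma; S.sigma = sigma; S.lam = lambda; S.dt = dt;
  S.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  S.bond_k = bond_k; S.bond_r0 = bond_r0;
  S.force_cap = force_cap;
  S.seed = static_cast<uint64_t>(seed);
  S.aij = aij.begin();
  S.ntypes = aij.nrow();
  S.setup_cells();
  for (int i = 0; i < n; ++i) S.wrap(i);

  std::vector<double> v_old(3 * n);

  List frames;
  std::vector<double> th_step, th_kT, th_px, th_py, th_pz, th_maxf;

  auto snapshot = [&](int step) {
    NumericMatrix p(n, 3), vv(n, 3);
    IntegerMatrix im(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        p(i, d) = S.x[3 * i + d];
        vv(i, d) = S.v[3 * i + d];
        im(i, d) = S.img[3 * i + d];
      }
    frames.push_back(List::create(_["step"] = step, _["positions"] = p,
                                  _["velocities"] = vv, _["images"] = im));
  };

  auto thermo = [&](int step) {
    double p[3] = {0, 0, 0};
    double maxf = 0.0;
    for (int i = 0; i < n; ++i) {
      double fm = 0.0;
      for (int d = 0; d < 3; ++d) {
        p[d] += S.v[3 * i + d];
        fm += S.f[3 * i + d] * S.f[3 * i + d];
      }
      if (fm > maxf) maxf = fm;
    }
    th_step.push_back(step);
    th_kT.push_back(S.kinetic_temperature());
    th_px.push_back(p[0]); th_py.push_back(p[1]); th_pz.push_back(p[2]);
    th_maxf.push_back(std::sqrt(maxf));
  };

  bool have_f0 = (f0.nrow() == n);
  if (have_f0) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) S.f[3 * i + d] = f0(i, d);
  } else {
    S.compute_forces(static_cast<uint64_t>(step0));
  }

  if (snapshot_every > 0) snapshot(step0);
  if (thermo_every > 0) thermo(step0);

  for (int s = 1; s <= n_steps; ++s) {
    int step = step0 + s;
    // position update + velocity prediction
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        int k = 3 * i + d;
        v_old[k] = S.v[k];
        S.x[k] += dt * S.v[k] + 0.5 * dt * dt * S.f[k];
        S.v[k] = v_old[k] + S.lam * dt * S.f[k];  // predicted velocity
      }
      S.wrap(i);
    }
    std::vector<double> f_old(S.f);
    S.compute_forces(static_cast<uint64_t>(step));
    // velocity correction
    for (int k = 0; k < 3 * n; ++k)
      S.v[k] = v_old[k] + 0.5 * dt * (f_old[k] + S.f[k]);

    if (snapshot_every > 0 && s % snapshot_every == 0) {
      check_finite(S, step);
      snapshot(step);
    }
    if (thermo_every > 0 && s % thermo_every == 0) {
      check_finite(S, step);
      thermo(step);
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  check_finite(S, step0 + n_steps);

  NumericMatrix pos_out(n, 3), vel_out(n, 3), f_out(n, 3);
  IntegerMatrix img_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = S.x[3 * i + d];
      vel_out(i, d) = S.v[3 * i + d];
      f_out(i, d) = S.f[3 * i + d];
      img_out(i, d) = S.img[3 * i + d];
    }
  int nth = th_step.size();
  NumericMatrix th(nth, 6);
  for (int r = 0; r < nth; ++r) {
    th(r, 0) = th_step[r]; th(r, 1) = th_kT[r];
    th(r, 2) = th_px[r]; th(r, 3) = th_py[r]; th(r, 4) = th_pz[r];
    th(r, 5) = th_maxf[r];
  }
  colnames(th) = CharacterVector::create("step", "kT", "px", "py", "pz",
                                         "max_force");
  return List::create(
    _["positions"] = pos_out, _["velocities"] = vel_out,
    _["images"] = img_out, _["forces"] = f_out,
    _["frames"] = frames, _["thermo"] = th,
    _["step"] = step0 + n_steps, _["used_cell_list"] = S.use_cells);
}

// ---------------------------------------------------------------------------
// Neighbour enumeration (exported for oracle testing): all minimum-image
// pairs with r < rc, via the same cell list as the force loop (all-pairs
// fallback when any box side < 3 rc). 1-based indices, i < j.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double rc) {
  int n = pos.nrow();
  DpdSystem S;
  S.n = n;
  S.x.resize(3 * n);
  S.v.assign(3 * n, 0.0);
  S.img.assign(3 * n, 0);
  S.type.assign(n, 0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) S.x[3 * i + d] = pos(i, d);
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.rc = rc; S.rc2 = rc * rc;
  S.setup_cells();
  for (int i = 0; i < n; ++i) S.wrap(i);

  std::vector<int> out_i, out_j;
  auto consider = [&](int i, int j) {
    double dx = S.x[3 * i] - S.x[3 * j];
    double dy = S.x[3 * i + 1] - S.x[3 * j + 1];
    double dz = S.x[3 * i + 2] - S.x[3 * j + 2];
    S.min_image(dx, dy, dz);
    if (dx * dx + dy * dy + dz * dz < S.rc2) {
      out_i.push_back(i < j ? i + 1 : j + 1);
      out_j.push_back(i < j ? j + 1 : i + 1);
    }
  };

  if (S.use_cells) {
    S.bin_particles();
    static const int stencil[13][3] = {
      {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
      {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
      {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
    for (int cz = 0; cz < S.nc[2]; ++cz)
      for (int cy = 0; cy < S.nc[1]; ++cy)
        for (int cx = 0; cx < S.nc[0]; ++cx) {
          int c = (cz * S.nc[1] + cy) * S.nc[0] + cx;
          for (int i = S.head[c]; i >= 0; i = S.nxt[i])
            for (int j = S.nxt[i]; j >= 0; j = S.nxt[j]) consider(i, j);
          for (int s = 0; s < 13; ++s) {
            int ox = (cx + stencil[s][0] + S.nc[0]) % S.nc[0];
            int oy = (cy + stencil[s][1] + S.nc[1]) % S.nc[1];
            int oz = (cz + stencil[s][2] + S.nc[2]) % S.nc[2];
            int c2 = (oz * S.nc[1] + oy) * S.nc[0] + ox;
            for (int i = S.head[c]; i >= 0; i = S.nxt[i])
              for (int j = S.head[c2]; j >= 0; j = S.nxt[j]) consider(i, j);
          }
        }
  } else {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  }

  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_temperature(NumericMatrix vel) {
  int n = vel.nrow();
  if (n < 2) stop("temperature requires at least 2 beads");
  double cm[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) cm[d] += vel(i, d);
  for (int d = 0; d < 3; ++d) cm[d] /= n;
  double sum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double dv = vel(i, d) - cm[d];
      sum += dv * dv;
    }
  return sum / (3.0 * (n - 1));
}
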