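// Minimal coarse-grained NPT molecular-dynamics core.
//
// Units: length nm, time ps, mass amu, energy kJ/mol, charge e.
// Nonbonded model: Lennard-Jones with potential shift at the cutoff and
// reaction-field electrostatics with a conductor boundary (eps_rf -> inf),
// both zero at and beyond the cutoff. Cubic periodic box, minimum image.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <functional>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double KB = 0.008314462618;     // kJ/mol/K
static const double FELEC = 138.935458;      // kJ mol^-1 nm e^-2
static const double PRESFAC = 16.6054;       // kJ/mol/nm^3 -> bar

// ---------------------------------------------------------------- RNG -----
// splitmix64-seeded xoshiro256+ with Box-Muller normals and Marsaglia-Tsang
// gamma deviates; self-contained so runs are reproducible under one seed.
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; i++) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t res = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return res;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th); have_spare = true;
    return r * std::cos(th);
  }
  // Gamma(shape a >= 0.5ish, scale 1); Marsaglia & Tsang, with boost for a < 1.
  double gamma(double a) {
    if (a < 1.0) {
      double u = unif();
      while (u <= 0.0) u = unif();
      return gamma(a + 1.0) * std::pow(u, 1.0 / a);
    }
    double d = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm(), v = 1.0 + c * x;
      if (v <= 0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

// -------------------------------------------------------------- helpers ---
static inline double pbc(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct Vec3 { double x, y, z; };

// Shared simulation data, kept in plain arrays for speed.
struct Model {
  int n = 0, ntypes = 0;
  std::vector<double> px, py, pz;     // positions
  std::vector<double> vx, vy, vz;     // velocities
  std::vector<double> mass, invm, charge;
  std::vector<int> type;
  double box = 0.0;
  // per type-pair tables (ntypes * ntypes), precomputed LJ coefficients
  std::vector<double> A, B, Vsh;      // 4 eps sig^12, 4 eps sig^6, shift
  bool any_charge = false;
  double rc = 1.1, rc2 = 1.21, eps_r = 15.0, krf = 0.0, crf = 0.0;
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_0, a_kf;
  std::vector<int> c_i, c_j; std::vector<double> c_d;
  // exclusions, CSR over sorted pairs (i < j)
  std::vector<int> excl_start, excl_idx;
  // neighbour list (parallel arrays: indices, type-pair slot, charge product)
  double rlist = 1.3;
  std::vector<int> nb_i, nb_j, nb_tp;
  std::vector<double> nb_qq;
  // scratch for the flat cell list
  std::vector<int> cell_of, cell_start, order;

  void push_pair(int i, int j) {
    nb_i.push_back(i); nb_j.push_back(j);
    nb_tp.push_back(type[i] * ntypes + type[j]);
    nb_qq.push_back(charge[i] * charge[j]);
  }

  bool excluded(int i, int j) const {
    if (i > j) std::swap(i, j);
    for (int k = excl_start[i]; k < excl_start[i + 1]; k++)
      if (excl_idx[k] == j) return true;
    return false;
  }

  void set_cutoff(double cutoff, double epsr, double skin) {
    rc = cutoff; rc2 = cutoff * cutoff; eps_r = epsr;
    krf = 1.0 / (2.0 * rc * rc * rc);     // conductor boundary
    crf = 3.0 / (2.0 * rc);
    rlist = rc + skin;
  }

  void build_pairs() {
    nb_i.clear(); nb_j.clear(); nb_tp.clear(); nb_qq.clear();
    double L = box;
    double rl2 = rlist * rlist;
    int nc = std::max(1, (int)std::floor(L / (rlist / 2)));
    {
      double cw0 = L / std::max(1, nc);
      int reach0 = (int)std::ceil(rlist / cw0);
      if (nc < 2 * reach0 + 1) nc = 0;  // stencil would wrap: brute force
    }
    if (nc < 3) { // brute force for small boxes
      for (int i = 0; i < n; i++)
        for (int j = i + 1; j < n; j++) {
          double dx = pbc(px[i] - px[j], L), dy = pbc(py[i] - py[j], L),
                 dz = pbc(pz[i] - pz[j], L);
          if (dx * dx + dy * dy + dz * dz < rl2 && !excluded(i, j))
            push_pair(i, j);
        }
      return;
    }
    // flat CSR cell list at roughly half the list radius: tighter stencil
    // volume means far fewer candidate distance checks
    double cw = L / nc;
    int reach = (int)std::ceil(rlist / cw);
    int ncell = nc * nc * nc;
    cell_of.resize(n);
    cell_start.assign(ncell + 1, 0);
    order.resize(n);
    auto cidx = [&](double a) {
      int c = (int)std::floor(a / cw);
      c %= nc; if (c < 0) c += nc;
      return c;
    };
    for (int i = 0; i < n; i++) {
      int c = (cidx(px[i]) * nc + cidx(py[i])) * nc + cidx(pz[i]);
      cell_of[i] = c;
      cell_start[c + 1]++;
    }
    for (int c = 0; c < ncell; c++) cell_start[c + 1] += cell_start[c];
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; i++) order[fill[cell_of[i]]++] = i;
    // half-space stencil (lexicographically positive offsets), pruned by the
    // minimal distance between cell pairs; guard against wrap double-count
    // when the stencil diameter reaches the box
    std::vector<std::array<int, 3>> st;
    for (int ox = -reach; ox <= reach; ox++)
      for (int oy = -reach; oy <= reach; oy++)
        for (int oz = -reach; oz <= reach; oz++) {
          if (oz < 0 || (oz == 0 && oy < 0) ||
              (oz == 0 && oy == 0 && ox < 0)) continue;
          double mind2 = 0;
          int off[3] = {ox, oy, oz};
          for (int d = 0; d < 3; d++) {
            double m = std::max(0, std::abs(off[d]) - 1) * cw;
            mind2 += m * m;
          }
          if (mind2 >= rl2) continue;
          st.push_back({ox, oy, oz});
        }
    // wrap tables avoid modulo arithmetic in the hot stencil loop
    std::vector<int> wrap(nc + 2 * reach + 1);
    for (int k = 0; k < (int)wrap.size(); k++) wrap[k] = (k - reach + nc) % nc;
    for (int cx = 0; cx < nc; cx++)
      for (int cy = 0; cy < nc; cy++)
        for (int cz = 0; cz < nc; cz++) {
          int c = (cx * nc + cy) * nc + cz;
          int a0 = cell_start[c], a1 = cell_start[c + 1];
          if (a0 == a1) continue;
          for (size_t s = 0; s < st.size(); s++) {
            int ox = wrap[cx + st[s][0] + reach],
                oy = wrap[cy + st[s][1] + reach],
                oz = wrap[cz + st[s][2] + reach];
            int c2 = (ox * nc + oy) * nc + oz;
            bool same = (c2 == c);
            int b0 = cell_start[c2], b1 = cell_start[c2 + 1];
            for (int ai = a0; ai < a1; ai++) {
              int i = order[ai];
              double xi = px[i], yi = py[i], zi = pz[i];
              int bj0 = same ? ai + 1 : b0;
              for (int bj = bj0; bj < b1; bj++) {
                int j = order[bj];
                double dx = pbc(xi - px[j], L), dy = pbc(yi - py[j], L),
                       dz = pbc(zi - pz[j], L);
                if (dx * dx + dy * dy + dz * dz < rl2 && !excluded(i, j))
                  push_pair(i, j);
              }
            }
          }
        }
  }

  // forces, potential energy and scalar virial; fx etc must be zeroed outside
  double forces(std::vector<double>& fx, std::vector<double>& fy,
                std::vector<double>& fz, double& virial,
                double clash_floor, int& n_clash) const {
    double L = box, epot = 0.0; virial = 0.0;
    const double cf2 = clash_floor * clash_floor;
    size_t np = nb_i.size();
    for (size_t p = 0; p < np; p++) {
      int i = nb_i[p], j = nb_j[p];
      double dx = pbc(px[i] - px[j], L), dy = pbc(py[i] - py[j], L),
             dz = pbc(pz[i] - pz[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 < cf2) n_clash++;
      int tp = nb_tp[p];
      double inv2 = 1.0 / r2, inv6 = inv2 * inv2 * inv2;
      double a = A[tp], b = B[tp];
      double e = (a * inv6 - b) * inv6 - Vsh[tp];
      double fr = (12.0 * a * inv6 - 6.0 * b) * inv6 * inv2; // F/r
      double qq = nb_qq[p];
      if (qq != 0.0) {
        double r = std::sqrt(r2), invr = 1.0 / r;
        double fq = FELEC * qq / eps_r;
        e += fq * (invr + krf * r2 - crf);
        fr += fq * (invr * inv2 - 2.0 * krf);
      }
      epot += e;
      virial += fr * r2;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // bonds
    for (size_t p = 0; p < b_i.size(); p++) {
      int i = b_i[p], j = b_j[p];
      double dx = pbc(px[i] - px[j], L), dy = pbc(py[i] - py[j], L),
             dz = pbc(pz[i] - pz[j], L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - b_0[p];
      epot += 0.5 * b_k[p] * dr * dr;
      double fr = -b_k[p] * dr / r;
      virial += fr * r * r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // harmonic angles
    for (size_t p = 0; p < a_i.size(); p++) {
      int i = a_i[p], j = a_j[p], k = a_k[p];
      double r1x = pbc(px[i] - px[j], L), r1y = pbc(py[i] - py[j], L),
             r1z = pbc(pz[i] - pz[j], L);
      double r2x = pbc(px[k] - px[j], L), r2y = pbc(py[k] - py[j], L),
             r2z = pbc(pz[k] - pz[j], L);
      double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      double ct = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct), dth = th - a_0[p];
      epot += 0.5 * a_kf[p] * dth * dth;
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double coef = -a_kf[p] * dth / st;
      // dcos/dri etc.
      double f1x = coef * (r2x / (n1 * n2) - ct * r1x / (n1 * n1));
      double f1y = coef * (r2y / (n1 * n2) - ct * r1y / (n1 * n1));
      double f1z = coef * (r2z / (n1 * n2) - ct * r1z / (n1 * n1));
      double f2x = coef * (r1x / (n1 * n2) - ct * r2x / (n2 * n2));
      double f2y = coef * (r1y / (n1 * n2) - ct * r2y / (n2 * n2));
      double f2z = coef * (r1z / (n1 * n2) - ct * r2z / (n2 * n2));
      fx[i] -= f1x; fy[i] -= f1y; fz[i] -= f1z;
      fx[k] -= f2x; fy[k] -= f2y; fz[k] -= f2z;
      fx[j] += f1x + f2x; fy[j] += f1y + f2y; fz[j] += f1z + f2z;
    }
    return epot;
  }

  // SHAKE on positions: reference geometry in (rx,ry,rz), updates p*.
  // Returns false on failure to converge.
  bool shake(const std::vector<double>& rx, const std::vector<double>& ry,
             const std::vector<double>& rz, double tol, int maxit) {
    double L = box;
    for (int it = 0; it < maxit; it++) {
      double worst = 0.0;
      for (size_t p = 0; p < c_i.size(); p++) {
        int i = c_i[p], j = c_j[p];
        double d = c_d[p], d2 = d * d;
        double dx = pbc(px[i] - px[j], L), dy = pbc(py[i] - py[j], L),
               dz = pbc(pz[i] - pz[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        double diff = r2 - d2;
        double rel = std::fabs(diff) / d2;
        if (rel > worst) worst = rel;
        if (rel > tol) {
          double sx = pbc(rx[i] - rx[j], L), sy = pbc(ry[i] - ry[j], L),
                 sz = pbc(rz[i] - rz[j], L);
          double dot = sx * dx + sy * dy + sz * dz;
          if (std::fabs(dot) < 1e-12) dot = (dot < 0 ? -1e-12 : 1e-12);
          double g = diff / (2.0 * dot * (invm[i] + invm[j]));
          px[i] -= g * invm[i] * sx; py[i] -= g * invm[i] * sy; pz[i] -= g * invm[i] * sz;
          px[j] += g * invm[j] * sx; py[j] += g * invm[j] * sy; pz[j] += g * invm[j] * sz;
        }
      }
      if (worst <= tol) return true;
    }
    return false;
  }

  void wrap() {
    for (int i = 0; i < n; i++) {
      px[i] -= box * std::floor(px[i] / box);
      py[i] -= box * std::floor(py[i] / box);
      pz[i] -= box * std::floor(pz[i] / box);
    }
  }

  double kinetic() const {
    double k = 0.0;
    for (int i = 0; i < n; i++)
      k += mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return 0.5 * k;
  }

  void remove_com_velocity() {
    double mx = 0, my = 0, mz = 0, M = 0;
    for (int i = 0; i < n; i++) {
      mx += mass[i] * vx[i]; my += mass[i] * vy[i]; mz += mass[i] * vz[i];
      M += mass[i];
    }
    mx /= M; my /= M; mz /= M;
    for (int i = 0; i < n; i++) { vx[i] -= mx; vy[i] -= my; vz[i] -= mz; }
  }
};

static Model make_model(const NumericMatrix& pos, const NumericMatrix& vel,
                        double box, const NumericVector& mass,
                        const NumericVector& charge, const IntegerVector& type,
                        int ntypes, const NumericVector& eps,
                        const NumericVector& sig, const List& bonded,
                        double cutoff, double eps_r, double skin) {
  Model m;
  m.n = pos.nrow(); m.box = box; m.ntypes = ntypes;
  m.px.resize(m.n); m.py.resize(m.n); m.pz.resize(m.n);
  m.vx.assign(m.n, 0.0); m.vy.assign(m.n, 0.0); m.vz.assign(m.n, 0.0);
  for (int i = 0; i < m.n; i++) {
    m.px[i] = pos(i, 0); m.py[i] = pos(i, 1); m.pz[i] = pos(i, 2);
  }
  if (vel.nrow() == m.n)
    for (int i = 0; i < m.n; i++) {
      m.vx[i] = vel(i, 0); m.vy[i] = vel(i, 1); m.vz[i] = vel(i, 2);
    }
  m.mass.resize(m.n); m.invm.resize(m.n); m.charge.resize(m.n); m.type.resize(m.n);
  for (int i = 0; i < m.n; i++) {
    m.mass[i] = mass[i]; m.invm[i] = 1.0 / mass[i];
    m.charge[i] = charge[i]; m.type[i] = type[i];
    if (charge[i] != 0.0) m.any_charge = true;
  }
  m.set_cutoff(cutoff, eps_r, skin);
  int nt2 = ntypes * ntypes;
  m.A.resize(nt2); m.B.resize(nt2); m.Vsh.resize(nt2);
  for (int t = 0; t < nt2; t++) {
    double e = eps[t], s = sig[t];
    double s6 = std::pow(s, 6);
    m.A[t] = 4.0 * e * s6 * s6;
    m.B[t] = 4.0 * e * s6;
    double ic2 = 1.0 / (cutoff * cutoff), ic6 = ic2 * ic2 * ic2;
    m.Vsh[t] = (m.A[t] * ic6 - m.B[t]) * ic6;
  }
  IntegerMatrix bonds = bonded["bonds_idx"];       // n x 2, 0-based
  NumericMatrix bpar = bonded["bonds_par"];        // b0, k
  for (int p = 0; p < bonds.nrow(); p++) {
    m.b_i.push_back(bonds(p, 0)); m.b_j.push_back(bonds(p, 1));
    m.b_0.push_back(bpar(p, 0)); m.b_k.push_back(bpar(p, 1));
  }
  IntegerMatrix angles = bonded["angles_idx"];     // n x 3
  NumericMatrix apar = bonded["angles_par"];       // theta0 (rad), k
  for (int p = 0; p < angles.nrow(); p++) {
    m.a_i.push_back(angles(p, 0)); m.a_j.push_back(angles(p, 1));
    m.a_k.push_back(angles(p, 2));
    m.a_0.push_back(apar(p, 0)); m.a_kf.push_back(apar(p, 1));
  }
  IntegerMatrix cons = bonded["cons_idx"];         // n x 2
  NumericVector cd = bonded["cons_d"];
  for (int p = 0; p < cons.nrow(); p++) {
    m.c_i.push_back(cons(p, 0)); m.c_j.push_back(cons(p, 1));
    m.c_d.push_back(cd[p]);
  }
  // exclusions CSR (pairs with i < j)
  IntegerMatrix ex = bonded["excl_idx"];
  std::vector<std::vector<int>> tmp(m.n);
  for (int p = 0; p < ex.nrow(); p++) {
    int i = ex(p, 0), j = ex(p, 1);
    if (i > j) std::swap(i, j);
    tmp[i].push_back(j);
  }
  m.excl_start.assign(m.n + 1, 0);
  for (int i = 0; i < m.n; i++) {
    std::sort(tmp[i].begin(), tmp[i].end());
    tmp[i].erase(std::unique(tmp[i].begin(), tmp[i].end()), tmp[i].end());
    m.excl_start[i + 1] = m.excl_start[i] + (int)tmp[i].size();
  }
  for (int i = 0; i < m.n; i++)
    for (int j : tmp[i]) m.excl_idx.push_back(j);
  return m;
}

// ------------------------------------------------------------ one-shot ----
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, double box, NumericVector mass,
                NumericVector charge, IntegerVector type, int ntypes,
                NumericVector eps, NumericVector sig, List bonded,
                double cutoff, double eps_r, double clash_floor) {
  NumericMatrix vel(0, 3);
  Model m = make_model(pos, vel, box, mass, charge, type, ntypes, eps, sig,
                       bonded, cutoff, eps_r, 0.0);
  m.build_pairs();
  std::vector<double> fx(m.n, 0.0), fy(m.n, 0.0), fz(m.n, 0.0);
  double vir = 0.0; int ncl = 0;
  double e = m.forces(fx, fy, fz, vir, clash_floor, ncl);
  NumericMatrix F(m.n, 3);
  for (int i = 0; i < m.n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["energy"] = e, _["forces"] = F, _["virial"] = vir,
                      _["n_clash"] = ncl);
}

// ---------------------------------------------------------- minimizer -----
// Steepest descent with adaptive step, GROMACS-style; SHAKE applied after
// each trial move so constrained geometries stay rigid.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, double box, NumericVector mass,
                  NumericVector charge, IntegerVector type, int ntypes,
                  NumericVector eps, NumericVector sig, List bonded,
                  double cutoff, double eps_r, int max_steps, double fmax_tol,
                  double init_step, double shake_tol) {
  NumericMatrix vel(0, 3);
  Model m = make_model(pos, vel, box, mass, charge, type, ntypes, eps, sig,
                       bonded, cutoff, eps_r, 0.1);
  m.build_pairs();
  std::vector<double> fx(m.n, 0.0), fy(m.n, 0.0), fz(m.n, 0.0);
  double vir; int ncl = 0;
  double e = m.forces(fx, fy, fz, vir, 0.0, ncl);
  double h = init_step;
  int step = 0;
  double fmax = 0.0;
  for (step = 0; step < max_steps; step++) {
    fmax = 0.0;
    for (int i = 0; i < m.n; i++) {
      double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i]);
      if (f > fmax) fmax = f;
    }
    if (fmax < fmax_tol) break;
    std::vector<double> ox = m.px, oy = m.py, oz = m.pz;
    double sc = h / fmax;
    for (int i = 0; i < m.n; i++) {
      m.px[i] += sc * fx[i]; m.py[i] += sc * fy[i]; m.pz[i] += sc * fz[i];
    }
    if (!m.c_i.empty()) m.shake(ox, oy, oz, shake_tol, 500);
    if (step % 10 == 0) m.build_pairs();
    std::vector<double> gx(m.n, 0.0), gy(m.n, 0.0), gz(m.n, 0.0);
    double e2 = m.forces(gx, gy, gz, vir, 0.0, ncl);
    if (!std::isfinite(e2))
      stop("minimization diverged (non-finite energy) at step %d", step);
    if (e2 < e) {
      e = e2; fx = gx; fy = gy; fz = gz; h = std::min(h * 1.2, 0.2);
    } else {
      m.px = ox; m.py = oy; m.pz = oz; h *= 0.2;
      if (h < 1e-8) break;
      m.build_pairs();
    }
  }
  m.wrap();
  NumericMatrix out(m.n, 3);
  for (int i = 0; i < m.n; i++) { out(i, 0) = m.px[i]; out(i, 1) = m.py[i]; out(i, 2) = m.pz[i]; }
  return List::create(_["positions"] = out, _["energy"] = e, _["fmax"] = fmax,
                      _["steps"] = step, _["converged"] = (fmax < fmax_tol));
}

// -------------------------------------------------------------- run MD ----
// Leapfrog + SHAKE + V-rescale (Bussi) thermostat + Berendsen barostat.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, double box,
                NumericVector mass, NumericVector charge, IntegerVector type,
                int ntypes, NumericVector eps, NumericVector sig, List bonded,
                List cfg, int nsteps, int stride, int seed) {
  double cutoff = as<double>(cfg["cutoff"]);
  double eps_r = as<double>(cfg["epsilon_r"]);
  double skin = as<double>(cfg["skin"]);
  int nlist_update = as<int>(cfg["nlist_update"]);
  double dt = as<double>(cfg["dt"]);                 // ps
  bool thermo = as<bool>(cfg["thermostat"]);
  bool baro = as<bool>(cfg["barostat"]);
  double T0 = as<double>(cfg["T0"]);
  double tau_T = as<double>(cfg["tau_T"]);
  double P0 = as<double>(cfg["P0"]);
  double tau_P = as<double>(cfg["tau_P"]);
  double kappa = as<double>(cfg["compressibility"]);
  double shake_tol = as<double>(cfg["constraint_tol"]);
  bool remove_com = as<bool>(cfg["remove_com"]);
  double clash_floor = as<double>(cfg["clash_floor"]);

  Model m = make_model(pos, vel, box, mass, charge, type, ntypes, eps, sig,
                       bonded, cutoff, eps_r, skin);
  Rng rng((uint64_t)seed);
  int ndof = 3 * m.n - (int)m.c_i.size() - (remove_com ? 3 : 0);
  if (ndof < 1) ndof = 1;
  double kt_target = 0.5 * ndof * KB * T0;

  m.build_pairs();
  std::vector<double> fx(m.n, 0.0), fy(m.n, 0.0), fz(m.n, 0.0);
  double vir = 0.0; int ncl = 0;
  double epot = m.forces(fx, fy, fz, vir, clash_floor, ncl);

  int nframes = nsteps / stride + 1;
  List fr_pos(nframes), fr_vel(nframes);
  NumericVector fr_box(nframes), fr_time(nframes);
  int nlog = nframes;
  NumericMatrix elog(nlog, 7); // time, Epot, Ekin, Etot, T, P, V
  int fidx = 0;

  // leapfrog full-step kinetic energy: average of the two half-step values
  double kin_prev = m.kinetic();
  auto record = [&](int step) {
    NumericMatrix P(m.n, 3), V(m.n, 3);
    Model tmp = m; tmp.wrap();
    for (int i = 0; i < m.n; i++) {
      P(i, 0) = tmp.px[i]; P(i, 1) = tmp.py[i]; P(i, 2) = tmp.pz[i];
      V(i, 0) = m.vx[i]; V(i, 1) = m.vy[i]; V(i, 2) = m.vz[i];
    }
    double ekin = step == 0 ? m.kinetic()
                            : 0.5 * (kin_prev + m.kinetic());
    double vol = m.box * m.box * m.box;
    double pres = (2.0 * ekin + vir) / (3.0 * vol) * PRESFAC;
    fr_pos[fidx] = P; fr_vel[fidx] = V;
    fr_box[fidx] = m.box; fr_time[fidx] = step * dt;
    elog(fidx, 0) = step * dt; elog(fidx, 1) = epot;
    elog(fidx, 2) = ekin; elog(fidx, 3) = epot + ekin;
    elog(fidx, 4) = 2.0 * ekin / (ndof * KB);
    elog(fidx, 5) = pres; elog(fidx, 6) = vol;
    fidx++;
  };
  record(0);

  for (int step = 1; step <= nsteps; step++) {
    if (step % stride == 0) kin_prev = m.kinetic();  // K(t - dt/2)
    // leapfrog kick
    for (int i = 0; i < m.n; i++) {
      m.vx[i] += fx[i] * m.invm[i] * dt;
      m.vy[i] += fy[i] * m.invm[i] * dt;
      m.vz[i] += fz[i] * m.invm[i] * dt;
    }
    // V-rescale thermostat (stochastic, Bussi 2007) on half-step velocities
    if (thermo) {
      double kin = m.kinetic();
      if (kin > 1e-12) {
        double c = std::exp(-dt / tau_T);
        double r1 = rng.norm();
        double r2 = 2.0 * rng.gamma(0.5 * (ndof - 1));
        double knew = kin + (1.0 - c) * (kt_target * (r1 * r1 + r2) / ndof - kin)
                      + 2.0 * r1 * std::sqrt(kin * kt_target / ndof * (1.0 - c) * c);
        if (knew < 0) knew = 0;
        double alpha = std::sqrt(knew / kin);
        for (int i = 0; i < m.n; i++) { m.vx[i] *= alpha; m.vy[i] *= alpha; m.vz[i] *= alpha; }
      }
    }
    // drift
    std::vector<double> ox = m.px, oy = m.py, oz = m.pz;
    for (int i = 0; i < m.n; i++) {
      m.px[i] += m.vx[i] * dt; m.py[i] += m.vy[i] * dt; m.pz[i] += m.vz[i] * dt;
    }
    if (!m.c_i.empty()) {
      if (!m.shake(ox, oy, oz, shake_tol, 500))
        stop("constraint solver failed to converge at step %d", step);
      // velocities from actual (constrained) displacement, minimum image
      for (int i = 0; i < m.n; i++) {
        m.vx[i] = pbc(m.px[i] - ox[i], m.box) / dt;
        m.vy[i] = pbc(m.py[i] - oy[i], m.box) / dt;
        m.vz[i] = pbc(m.pz[i] - oz[i], m.box) / dt;
      }
    }
    if (remove_com) m.remove_com_velocity();

    // forces at new positions
    if (step % nlist_update == 0) { m.wrap(); m.build_pairs(); }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    ncl = 0;
    epot = m.forces(fx, fy, fz, vir, clash_floor, ncl);
    if (!std::isfinite(epot)) {
      double mx = 0;
      for (int i = 0; i < m.n; i++)
        mx = std::max(mx, std::fabs(m.px[i] - ox[i]));
      stop("simulation blew up at step %d (max displacement %.3g nm)", step, mx);
    }

    // Berendsen isotropic barostat (positions + box scaled)
    if (baro) {
      double ekin = m.kinetic();
      double vol = m.box * m.box * m.box;
      double pres = (2.0 * ekin + vir) / (3.0 * vol) * PRESFAC;
      double mu = std::cbrt(1.0 - dt / tau_P * kappa * (P0 - pres));
      if (mu < 0.98) mu = 0.98;
      if (mu > 1.02) mu = 1.02;
      m.box *= mu;
      for (int i = 0; i < m.n; i++) { m.px[i] *= mu; m.py[i] *= mu; m.pz[i] *= mu; }
      // the isotropic scaling stretches rigid geometries; restore them
      if (!m.c_i.empty() && mu != 1.0) {
        std::vector<double> rx = m.px, ry = m.py, rz = m.pz;
        m.shake(rx, ry, rz, shake_tol, 500);
      }
    }

    if (step % stride == 0) record(step);
  }

  colnames(elog) = CharacterVector::create("time_ps", "epot", "ekin", "etot",
                                           "temperature", "pressure", "volume");
  NumericMatrix vfin(m.n, 3);
  for (int i = 0; i < m.n; i++) {
    vfin(i, 0) = m.vx[i]; vfin(i, 1) = m.vy[i]; vfin(i, 2) = m.vz[i];
  }
  return List::create(_["frames"] = fr_pos, _["velocities"] = fr_vel,
                      _["boxes"] = fr_box, _["times"] = fr_time,
                      _["energies"] = elog, _["final_velocities"] = vfin,
                      _["ndof"] = ndof);
}

// ----------------------------------------------------- molecule packing ---
// Random rigid-body insertion with a minimum inter-molecule bead distance.
// [[Rcpp::export]]
List cpp_insert_molecules(NumericMatrix tmpl, int count, double box,
                          double mindist, int seed, int max_tries) {
  int m = tmpl.nrow();
  Rng rng((uint64_t)seed);
  std::vector<double> X, Y, Z;   // accepted beads
  NumericMatrix out(count * m, 3);
  double md2 = mindist * mindist;
  int placed = 0;
  for (int mol = 0; mol < count; mol++) {
    bool ok = false;
    for (int t = 0; t < max_tries && !ok; t++) {
      // random rotation via quaternion
      double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
      double q0 = std::sqrt(1 - u1) * std::sin(2 * M_PI * u2);
      double q1 = std::sqrt(1 - u1) * std::cos(2 * M_PI * u2);
      double q2 = std::sqrt(u1) * std::sin(2 * M_PI * u3);
      double q3 = std::sqrt(u1) * std::cos(2 * M_PI * u3);
      double R[3][3] = {
        {1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2)},
        {2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1)},
        {2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)}};
      double tx = rng.unif() * box, ty = rng.unif() * box, tz = rng.unif() * box;
      std::vector<double> cx(m), cy(m), cz(m);
      for (int i = 0; i < m; i++) {
        double x = tmpl(i, 0), y = tmpl(i, 1), z = tmpl(i, 2);
        cx[i] = R[0][0] * x + R[0][1] * y + R[0][2] * z + tx;
        cy[i] = R[1][0] * x + R[1][1] * y + R[1][2] * z + ty;
        cz[i] = R[2][0] * x + R[2][1] * y + R[2][2] * z + tz;
      }
      bool clash = false;
      for (int i = 0; i < m && !clash; i++)
        for (size_t j = 0; j < X.size(); j++) {
          double dx = pbc(cx[i] - X[j], box), dy = pbc(cy[i] - Y[j], box),
                 dz = pbc(cz[i] - Z[j], box);
          if (dx * dx + dy * dy + dz * dz < md2) { clash = true; break; }
        }
      if (!clash) {
        for (int i = 0; i < m; i++) {
          double wx = cx[i] - box * std::floor(cx[i] / box);
          double wy = cy[i] - box * std::floor(cy[i] / box);
          double wz = cz[i] - box * std::floor(cz[i] / box);
          out(placed * m + i, 0) = wx; out(placed * m + i, 1) = wy;
          out(placed * m + i, 2) = wz;
          X.push_back(wx); Y.push_back(wy); Z.push_back(wz);
        }
        placed++; ok = true;
      }
    }
    if (!ok) break;
  }
  return List::create(_["positions"] = out, _["placed"] = placed);
}

// -------------------------------------------------------------- SASA ------
// Shrake-Rupley with a deterministic golden-spiral point set; PBC-aware.
// [[Rcpp::export]]
List cpp_sasa(NumericMatrix pos, NumericVector radii, double probe,
              int npoints, double box) {
  int n = pos.nrow();
  // golden spiral unit sphere points
  std::vector<double> sx(npoints), sy(npoints), sz(npoints);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; k++) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    sx[k] = r * std::cos(th); sy[k] = r * std::sin(th); sz[k] = z;
  }
  NumericVector area(n);
  double total = 0.0;
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, radii[i] + probe);
  for (int i = 0; i < n; i++) {
    double Ri = radii[i] + probe;
    // neighbours
    std::vector<int> nb;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1), dz = pos(i,2) - pos(j,2);
      if (box > 0) { dx = pbc(dx, box); dy = pbc(dy, box); dz = pbc(dz, box); }
      double Rj = radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < (Ri + Rj) * (Ri + Rj)) nb.push_back(j);
    }
    int nacc = 0;
    for (int k = 0; k < npoints; k++) {
      double qx = pos(i,0) + Ri * sx[k], qy = pos(i,1) + Ri * sy[k], qz = pos(i,2) + Ri * sz[k];
      bool buried = false;
      for (int j : nb) {
        double dx = qx - pos(j,0), dy = qy - pos(j,1), dz = qz - pos(j,2);
        if (box > 0) { dx = pbc(dx, box); dy = pbc(dy, box); dz = pbc(dz, box); }
        double Rj = radii[j] + probe;
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) nacc++;
    }
    double a = 4.0 * M_PI * Ri * Ri * nacc / npoints;
    area[i] = a; total += a;
  }
  return List::create(_["total"] = total, _["per_bead"] = area);
}

// ----------------------------------------------- pairwise distances -------
// Minimum-image pair distances (for RDF and small-system oracles).
// [[Rcpp::export]]
NumericVector cpp_pair_dists(NumericMatrix pos, double box) {
  int n = pos.nrow();
  NumericVector out((R_xlen_t)n * (n - 1) / 2);
  R_xlen_t q = 0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1), dz = pos(i,2) - pos(j,2);
      if (box > 0) { dx = pbc(dx, box); dy = pbc(dy, box); dz = pbc(dz, box); }
      out[q++] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return out;
}

// ------------------------------------------- molecule clustering ----------
// Union-find single-linkage clustering of molecules: two molecules are linked
// when any bead pair is closer than cutoff (minimum image).
// [[Rcpp::export]]
IntegerVector cpp_cluster_molecules(NumericMatrix pos, IntegerVector molid,
                                    double box, double cutoff) {
  int n = pos.nrow();
  int nmol = 0;
  for (int i = 0; i < n; i++) nmol = std::max(nmol, molid[i] + 1);
  std::vector<int> parent(nmol);
  for (int i = 0; i < nmol; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  double c2 = cutoff * cutoff;
  // cell list over beads
  int nc = std::max(1, (int)std::floor(box / cutoff));
  if (nc < 3) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        if (molid[i] == molid[j]) continue;
        double dx = pbc(pos(i,0) - pos(j,0), box), dy = pbc(pos(i,1) - pos(j,1), box),
               dz = pbc(pos(i,2) - pos(j,2), box);
        if (dx*dx + dy*dy + dz*dz < c2) {
          int a = find(molid[i]), b = find(molid[j]);
          if (a != b) parent[a] = b;
        }
      }
  } else {
    double cw = box / nc;
    std::vector<int> head(nc * nc * nc, -1), nxt(n, -1);
    auto cidx = [&](double a) {
      int c = (int)std::floor(a / cw); c %= nc; if (c < 0) c += nc; return c;
    };
    for (int i = 0; i < n; i++) {
      int c = (cidx(pos(i,0)) * nc + cidx(pos(i,1))) * nc + cidx(pos(i,2));
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; i++) {
      int cx = cidx(pos(i,0)), cy = cidx(pos(i,1)), cz = cidx(pos(i,2));
      for (int ox = -1; ox <= 1; ox++)
        for (int oy = -1; oy <= 1; oy++)
          for (int oz = -1; oz <= 1; oz++) {
            int c = (((cx + ox + nc) % nc) * nc + (cy + oy + nc) % nc) * nc +
                    (cz + oz + nc) % nc;
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              if (j <= i || molid[i] == molid[j]) continue;
              double dx = pbc(pos(i,0) - pos(j,0), box),
                     dy = pbc(pos(i,1) - pos(j,1), box),
                     dz = pbc(pos(i,2) - pos(j,2), box);
              if (dx*dx + dy*dy + dz*dz < c2) {
                int a = find(molid[i]), b = find(molid[j]);
                if (a != b) parent[a] = b;
              }
            }
          }
    }
  }
  IntegerVector lab(nmol);
  std::vector<int> remap(nmol, -1);
  int next = 0;
  for (int i = 0; i < nmol; i++) {
    int r = find(i);
    if (remap[r] < 0) remap[r] = next++;
    lab[i] = remap[r];
  }
  return lab;
}

// ----------------------------------------------- cluster unwrapping -------
// Connected components over the bead graph (pairs closer than cutoff,
// minimum image) and BFS unwrapping: each bead is placed next to its BFS
// parent so components become contiguous in unwrapped coordinates.
// [[Rcpp::export]]
List cpp_unwrap_components(NumericMatrix pos, double box, double cutoff) {
  int n = pos.nrow();
  double c2 = cutoff * cutoff;
  // adjacency via cell list
  std::vector<std::vector<int>> adj(n);
  int nc = std::max(1, (int)std::floor(box / cutoff));
  auto link = [&](int i, int j) { adj[i].push_back(j); adj[j].push_back(i); };
  if (nc < 3) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double dx = pbc(pos(i,0)-pos(j,0), box), dy = pbc(pos(i,1)-pos(j,1), box),
               dz = pbc(pos(i,2)-pos(j,2), box);
        if (dx*dx+dy*dy+dz*dz < c2) link(i, j);
      }
  } else {
    double cw = box / nc;
    std::vector<int> head(nc*nc*nc, -1), nxt(n, -1);
    auto ci = [&](double a){ int c=(int)std::floor(a/cw); c%=nc; if(c<0)c+=nc; return c; };
    for (int i = 0; i < n; i++) {
      int c = (ci(pos(i,0))*nc + ci(pos(i,1)))*nc + ci(pos(i,2));
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; i++) {
      int cx = ci(pos(i,0)), cy = ci(pos(i,1)), cz = ci(pos(i,2));
      for (int ox = -1; ox <= 1; ox++)
        for (int oy = -1; oy <= 1; oy++)
          for (int oz = -1; oz <= 1; oz++) {
            int c = (((cx+ox+nc)%nc)*nc + (cy+oy+nc)%nc)*nc + (cz+oz+nc)%nc;
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = pbc(pos(i,0)-pos(j,0), box),
                     dy = pbc(pos(i,1)-pos(j,1), box),
                     dz = pbc(pos(i,2)-pos(j,2), box);
              if (dx*dx+dy*dy+dz*dz < c2) link(i, j);
            }
          }
    }
  }
  IntegerVector comp(n, -1);
  NumericMatrix un(n, 3);
  int nextc = 0;
  std::vector<int> queue;
  for (int s = 0; s < n; s++) {
    if (comp[s] >= 0) continue;
    comp[s] = nextc;
    un(s,0) = pos(s,0); un(s,1) = pos(s,1); un(s,2) = pos(s,2);
    queue.clear(); queue.push_back(s);
    while (!queue.empty()) {
      int i = queue.back(); queue.pop_back();
      for (int j : adj[i]) {
        if (comp[j] >= 0) continue;
        comp[j] = nextc;
        un(j,0) = un(i,0) + pbc(pos(j,0)-pos(i,0), box);
        un(j,1) = un(i,1) + pbc(pos(j,1)-pos(i,1), box);
        un(j,2) = un(i,2) + pbc(pos(j,2)-pos(i,2), box);
        queue.push_back(j);
      }
    }
    nextc++;
  }
  return List::create(_["component"] = comp, _["unwrapped"] = un);
}
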