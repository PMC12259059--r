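// Compiled kernels: Ashbaugh-Hatch + bonded force field, cell-list neighbor
// search, and a BAOAB Langevin integrator.  All quantities here are in
// internal units: Angstrom, kcal/mol, g/mol, and the derived time unit
// tau = sqrt(g * A^2 * mol / kcal) ~ 48.888 fs.  Unit conversion happens in R.
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 0.0019872041;       // kcal/mol/K
static const double RMIN_FAC = 1.1224620483093730; // 2^(1/6)

// ---------------------------------------------------------------------------
// force-field parameter bundle
// ---------------------------------------------------------------------------
struct FFParams {
  int nt;                       // number of species
  std::vector<double> sig;      // nt*nt pair sigma (arithmetic mean)
  std::vector<double> lam;      // nt*nt lambda matrix
  std::vector<double> rc;       // nt*nt pair cutoff
  std::vector<double> shift;    // nt*nt energy shift so U(rc) = 0
  double eps, kb, r0, kth, th0;
  double rc_max;
};

static FFParams make_params(List model) {
  FFParams p;
  NumericVector sigma = model["sigma"];
  NumericMatrix lambda = model["lambda"];
  p.nt = sigma.size();
  p.eps = as<double>(model["epsilon"]);
  double cutfac = as<double>(model["cutoff_factor"]);
  p.kb = as<double>(model["k_bond"]);
  p.r0 = as<double>(model["r0"]);
  p.kth = as<double>(model["k_angle"]);
  p.th0 = as<double>(model["theta0"]);
  p.sig.resize(p.nt * p.nt);
  p.lam.resize(p.nt * p.nt);
  p.rc.resize(p.nt * p.nt);
  p.shift.resize(p.nt * p.nt);
  p.rc_max = 0.0;
  // U_LJ at the cutoff depends only on the cutoff factor
  double icf6 = std::pow(1.0 / cutfac, 6);
  double ulj_cut = 4.0 * p.eps * (icf6 * icf6 - icf6);
  for (int a = 0; a < p.nt; ++a)
    for (int b = 0; b < p.nt; ++b) {
      double s = 0.5 * (sigma[a] + sigma[b]);
      int k = a * p.nt + b;
      p.sig[k] = s;
      p.lam[k] = lambda(a, b);
      p.rc[k] = cutfac * s;
      p.shift[k] = lambda(a, b) * ulj_cut;
      if (p.rc[k] > p.rc_max) p.rc_max = p.rc[k];
    }
  return p;
}

static inline double min_image(double d, double box) {
  return d - box * std::round(d / box);
}

// Ashbaugh-Hatch pair energy and force magnitude (f = -dU/dr), shifted so
// that U(rc) = 0.  lambda scales only the attractive branch.
static inline void ah_pair(double r, double sig, double lam, double eps,
                           double shift, double &u, double &f) {
  double sr2 = (sig / r) * (sig / r);
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double ulj = 4.0 * eps * (sr12 - sr6);
  double fl = 4.0 * eps * (12.0 * sr12 - 6.0 * sr6) / r; // -dU_LJ/dr
  if (r <= RMIN_FAC * sig) {
    u = ulj + (1.0 - lam) * eps - shift;
    f = fl;
  } else {
    u = lam * ulj - shift;
    f = lam * fl;
  }
}

// ---------------------------------------------------------------------------
// neighbor list (cell list, falls back to O(N^2) for small boxes)
// ---------------------------------------------------------------------------
struct NeighborList {
  std::vector<int> i, j;
  std::vector<double> ref;      // positions at build time (wrapped)
  double rlist;                 // rc_max + skin
};

static inline long long pair_key(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * n + hi;
}

static void build_neighbors(const std::vector<double> &x, int n, double box,
                            const FFParams &p, const std::vector<int> &type,
                            const std::unordered_set<long long> &excl,
                            double skin, NeighborList &nl) {
  nl.i.clear(); nl.j.clear();
  nl.rlist = p.rc_max + skin;
  nl.ref = x;
  int nc = (int)std::floor(box / nl.rlist);
  if (nc >= 3) {
    double cell = box / nc;
    int ncell = nc * nc * nc;
    std::vector<int> head(ncell, -1), next(n, -1);
    std::vector<int> cix(n), ciy(n), ciz(n);
    for (int a = 0; a < n; ++a) {
      int ix = (int)std::floor(x[3 * a] / cell) % nc;     if (ix < 0) ix += nc;
      int iy = (int)std::floor(x[3 * a + 1] / cell) % nc; if (iy < 0) iy += nc;
      int iz = (int)std::floor(x[3 * a + 2] / cell) % nc; if (iz < 0) iz += nc;
      cix[a] = ix; ciy[a] = iy; ciz[a] = iz;
      int c = (ix * nc + iy) * nc + iz;
      next[a] = head[c]; head[c] = a;
    }
    for (int a = 0; a < n; ++a) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int ix = (cix[a] + dx + nc) % nc;
            int iy = (ciy[a] + dy + nc) % nc;
            int iz = (ciz[a] + dz + nc) % nc;
            int c = (ix * nc + iy) * nc + iz;
            for (int b = head[c]; b >= 0; b = next[b]) {
              if (b <= a) continue;
              double ddx = min_image(x[3 * a] - x[3 * b], box);
              double ddy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
              double ddz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              int k = type[a] * p.nt + type[b];
              double rl = p.rc[k] + skin;
              if (d2 <= rl * rl && !excl.count(pair_key(a, b, n))) {
                nl.i.push_back(a); nl.j.push_back(b);
              }
            }
          }
    }
  } else {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double ddx = min_image(x[3 * a] - x[3 * b], box);
        double ddy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
        double ddz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        int k = type[a] * p.nt + type[b];
        double rl = p.rc[k] + skin;
        if (d2 <= rl * rl && !excl.count(pair_key(a, b, n)))
          { nl.i.push_back(a); nl.j.push_back(b); }
      }
  }
}

// max displacement (squared) of any particle since the list was built
static double max_disp2(const std::vector<double> &x,
                        const NeighborList &nl, int n, double box) {
  double m = 0.0;
  for (int a = 0; a < n; ++a) {
    double dx = min_image(x[3 * a] - nl.ref[3 * a], box);
    double dy = min_image(x[3 * a + 1] - nl.ref[3 * a + 1], box);
    double dz = min_image(x[3 * a + 2] - nl.ref[3 * a + 2], box);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > m) m = d2;
  }
  return m;
}

// ---------------------------------------------------------------------------
// force evaluation
// ---------------------------------------------------------------------------
struct EnergyTerms { double bond, angle, pair; };

static EnergyTerms compute_forces(const std::vector<double> &x, int n,
                                  double box, const FFParams &p,
                                  const std::vector<int> &type,
                                  const IntegerMatrix &bonds,
                                  const IntegerMatrix &angles,
                                  const NeighborList &nl,
                                  std::vector<double> &f) {
  EnergyTerms e = {0.0, 0.0, 0.0};
  std::fill(f.begin(), f.end(), 0.0);

  // nonbonded
  size_t np = nl.i.size();
  for (size_t q = 0; q < np; ++q) {
    int a = nl.i[q], b = nl.j[q];
    double dx = min_image(x[3 * a] - x[3 * b], box);
    double dy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
    double dz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
    double r2 = dx * dx + dy * dy + dz * dz;
    int k = type[a] * p.nt + type[b];
    if (r2 >= p.rc[k] * p.rc[k]) continue;
    double r = std::sqrt(r2);
    if (r < 1e-10) stop("particle overlap (r ~ 0) between %d and %d", a, b);
    double u, fm;
    ah_pair(r, p.sig[k], p.lam[k], p.eps, p.shift[k], u, fm);
    e.pair += u;
    double fx = fm * dx / r, fy = fm * dy / r, fz = fm * dz / r;
    f[3 * a] += fx; f[3 * a + 1] += fy; f[3 * a + 2] += fz;
    f[3 * b] -= fx; f[3 * b + 1] -= fy; f[3 * b + 2] -= fz;
  }

  // bonds: U = Kb (r - r0)^2
  for (int q = 0; q < bonds.nrow(); ++q) {
    int a = bonds(q, 0), b = bonds(q, 1);
    double dx = min_image(x[3 * a] - x[3 * b], box);
    double dy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
    double dz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-10) stop("zero-length bond");
    double d = r - p.r0;
    e.bond += p.kb * d * d;
    double fm = -2.0 * p.kb * d;   // -dU/dr
    double fx = fm * dx / r, fy = fm * dy / r, fz = fm * dz / r;
    f[3 * a] += fx; f[3 * a + 1] += fy; f[3 * a + 2] += fz;
    f[3 * b] -= fx; f[3 * b + 1] -= fy; f[3 * b + 2] -= fz;
  }

  // angles: U = Kth (theta - th0)^2, central bead is the middle index
  for (int q = 0; q < angles.nrow(); ++q) {
    int ia = angles(q, 0), ij = angles(q, 1), ik = angles(q, 2);
    double ax = min_image(x[3 * ia] - x[3 * ij], box);
    double ay = min_image(x[3 * ia + 1] - x[3 * ij + 1], box);
    double az = min_image(x[3 * ia + 2] - x[3 * ij + 2], box);
    double bx = min_image(x[3 * ik] - x[3 * ij], box);
    double by = min_image(x[3 * ik + 1] - x[3 * ij + 1], box);
    double bz = min_image(x[3 * ik + 2] - x[3 * ij + 2], box);
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb = std::sqrt(bx * bx + by * by + bz * bz);
    double c = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;          // guard colinear triplets
    double th = std::acos(c);
    double dU = 2.0 * p.kth * (th - p.th0);
    e.angle += p.kth * (th - p.th0) * (th - p.th0);
    double coef = -dU / s;           // dU/dcos(theta)
    double fax = -coef * (bx / (ra * rb) - c * ax / (ra * ra));
    double fay = -coef * (by / (ra * rb) - c * ay / (ra * ra));
    double faz = -coef * (bz / (ra * rb) - c * az / (ra * ra));
    double fkx = -coef * (ax / (ra * rb) - c * bx / (rb * rb));
    double fky = -coef * (ay / (ra * rb) - c * by / (rb * rb));
    double fkz = -coef * (az / (ra * rb) - c * bz / (rb * rb));
    f[3 * ia] += fax; f[3 * ia + 1] += fay; f[3 * ia + 2] += faz;
    f[3 * ik] += fkx; f[3 * ik + 1] += fky; f[3 * ik + 2] += fkz;
    f[3 * ij] -= fax + fkx; f[3 * ij + 1] -= fay + fky; f[3 * ij + 2] -= faz + fkz;
  }
  return e;
}

// ---------------------------------------------------------------------------
// counter-based RNG: Gaussian noise keyed by (seed, step, particle), so the
// noise stream is independent of evaluation order and exactly restartable.
// ---------------------------------------------------------------------------
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t x) {
  return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline void gauss3(uint64_t seed, uint64_t step, uint64_t particle,
                          double *z) {
  uint64_t base = sm64(sm64(sm64(seed) ^ step) ^ (particle * 0x9E3779B97f4A7C15ULL));
  double u1 = u01(sm64(base ^ 1)), u2 = u01(sm64(base ^ 2));
  double u3 = u01(sm64(base ^ 3)), u4 = u01(sm64(base ^ 4));
  double r1 = std::sqrt(-2.0 * std::log(u1));
  double r2 = std::sqrt(-2.0 * std::log(u3));
  z[0] = r1 * std::cos(2.0 * M_PI * u2);
  z[1] = r1 * std::sin(2.0 * M_PI * u2);
  z[2] = r2 * std::cos(2.0 * M_PI * u4);
}

static std::unordered_set<long long> excl_set(const IntegerMatrix &excl, int n) {
  std::unordered_set<long long> s;
  for (int q = 0; q < excl.nrow(); ++q)
    s.insert(pair_key(excl(q, 0), excl(q, 1), n));
  return s;
}

// ---------------------------------------------------------------------------
// exported: single-point energy/forces
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector type, List model,
                       IntegerMatrix bonds, IntegerMatrix angles,
                       IntegerMatrix excl, double box) {
  int n = pos.nrow();
  FFParams p = make_params(model);
  std::vector<double> x(3 * n);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) x[3 * a + d] = pos(a, d);
  std::vector<int> ty(type.begin(), type.end());
  std::unordered_set<long long> ex = excl_set(excl, n);
  NeighborList nl;
  build_neighbors(x, n, box, p, ty, ex, 0.0, nl);
  std::vector<double> f(3 * n);
  EnergyTerms e = compute_forces(x, n, box, p, ty, bonds, angles, nl, f);
  NumericMatrix fout(n, 3);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) fout(a, d) = f[3 * a + d];
  return List::create(_["bond"] = e.bond, _["angle"] = e.angle,
                      _["pair"] = e.pair,
                      _["total"] = e.bond + e.angle + e.pair,
                      _["forces"] = fout);
}

// exported: all pairs within a single cutoff (inclusive), minimum image
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double box, double cutoff) {
  int n = pos.nrow();
  std::vector<int> pi, pj;
  int nc = (int)std::floor(box / cutoff);
  std::vector<double> x(3 * n);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) x[3 * a + d] = pos(a, d);
  double c2 = cutoff * cutoff;
  if (nc >= 3 && n > 200) {
    double cell = box / nc;
    int ncell = nc * nc * nc;
    std::vector<int> head(ncell, -1), nxt(n, -1), cx(n), cy(n), cz(n);
    for (int a = 0; a < n; ++a) {
      int ix = (int)std::floor(x[3 * a] / cell) % nc;     if (ix < 0) ix += nc;
      int iy = (int)std::floor(x[3 * a + 1] / cell) % nc; if (iy < 0) iy += nc;
      int iz = (int)std::floor(x[3 * a + 2] / cell) % nc; if (iz < 0) iz += nc;
      cx[a] = ix; cy[a] = iy; cz[a] = iz;
      int c = (ix * nc + iy) * nc + iz;
      nxt[a] = head[c]; head[c] = a;
    }
    for (int a = 0; a < n; ++a)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int c = (((cx[a] + dx + nc) % nc) * nc + (cy[a] + dy + nc) % nc) * nc
                    + (cz[a] + dz + nc) % nc;
            for (int b = head[c]; b >= 0; b = nxt[b]) {
              if (b <= a) continue;
              double ddx = min_image(x[3 * a] - x[3 * b], box);
              double ddy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
              double ddz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
                pi.push_back(a + 1); pj.push_back(b + 1);
              }
            }
          }
  } else {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double ddx = min_image(x[3 * a] - x[3 * b], box);
        double ddy = min_image(x[3 * a + 1] - x[3 * b + 1], box);
        double ddz = min_image(x[3 * a + 2] - x[3 * b + 2], box);
        if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
          pi.push_back(a + 1); pj.push_back(b + 1);
        }
      }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t q = 0; q < pi.size(); ++q) { out(q, 0) = pi[q]; out(q, 1) = pj[q]; }
  return out;
}

// ---------------------------------------------------------------------------
// exported: BAOAB Langevin / NVE velocity-Verlet run
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericMatrix vel0, IntegerMatrix img0,
                      IntegerVector type, List model,
                      IntegerMatrix bonds, IntegerMatrix angles,
                      IntegerMatrix excl, NumericVector mass,
                      double box, double dt, double temperature, double tdamp,
                      int nsteps, int cadence, int seed, int step0,
                      bool nve, double force_cap, double skin) {
  int n = pos0.nrow();
  FFParams p = make_params(model);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  std::vector<int> img(3 * n);
  std::vector<int> ty(type.begin(), type.end());
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) {
      x[3 * a + d] = pos0(a, d);
      v[3 * a + d] = vel0(a, d);
      img[3 * a + d] = img0(a, d);
    }
  std::unordered_set<long long> ex = excl_set(excl, n);
  if (p.rc_max + skin > box / 2.0)
    stop("cutoff + skin exceeds half the box edge");
  NeighborList nl;
  build_neighbors(x, n, box, p, ty, ex, skin, nl);
  EnergyTerms e = compute_forces(x, n, box, p, ty, bonds, angles, nl, f);

  double c1 = std::exp(-dt / tdamp);
  double c2 = std::sqrt(1.0 - c1 * c1);

  auto cap_forces = [&](void) {
    if (force_cap <= 0.0) return;
    for (int a = 0; a < n; ++a) {
      double fm = std::sqrt(f[3 * a] * f[3 * a] + f[3 * a + 1] * f[3 * a + 1] +
                            f[3 * a + 2] * f[3 * a + 2]);
      if (fm > force_cap) {
        double sc = force_cap / fm;
        f[3 * a] *= sc; f[3 * a + 1] *= sc; f[3 * a + 2] *= sc;
      }
    }
  };
  cap_forces();

  int nframes = nsteps / cadence + 1;
  List frames_pos(nframes), frames_img(nframes);
  IntegerVector frame_step(nframes);
  NumericMatrix elog(nframes, 5); // step, ekin, ebond, eangle, epair
  colnames(elog) = CharacterVector::create("step", "ekin", "bond", "angle", "pair");

  auto record = [&](int slot, int step) {
    NumericMatrix pm(n, 3);
    IntegerMatrix im(n, 3);
    double ekin = 0.0;
    for (int a = 0; a < n; ++a) {
      for (int d = 0; d < 3; ++d) {
        pm(a, d) = x[3 * a + d];
        im(a, d) = img[3 * a + d];
      }
      ekin += 0.5 * mass[a] * (v[3 * a] * v[3 * a] + v[3 * a + 1] * v[3 * a + 1] +
                               v[3 * a + 2] * v[3 * a + 2]);
    }
    frames_pos[slot] = pm;
    frames_img[slot] = im;
    frame_step[slot] = step;
    elog(slot, 0) = step; elog(slot, 1) = ekin;
    elog(slot, 2) = e.bond; elog(slot, 3) = e.angle; elog(slot, 4) = e.pair;
  };
  record(0, step0);

  int slot = 1;
  for (int s = 1; s <= nsteps; ++s) {
    uint64_t gstep = (uint64_t)(step0 + s);
    // B
    for (int a = 0; a < n; ++a) {
      double hm = 0.5 * dt / mass[a];
      v[3 * a] += hm * f[3 * a];
      v[3 * a + 1] += hm * f[3 * a + 1];
      v[3 * a + 2] += hm * f[3 * a + 2];
    }
    // A
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];
    // O
    if (!nve) {
      for (int a = 0; a < n; ++a) {
        double z[3];
        gauss3((uint64_t)seed, gstep, (uint64_t)a, z);
        double sd = std::sqrt(KB * temperature / mass[a]);
        v[3 * a] = c1 * v[3 * a] + c2 * sd * z[0];
        v[3 * a + 1] = c1 * v[3 * a + 1] + c2 * sd * z[1];
        v[3 * a + 2] = c1 * v[3 * a + 2] + c2 * sd * z[2];
      }
    }
    // A
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];
    // wrap
    for (int q = 0; q < 3 * n; ++q) {
      double w = std::floor(x[q] / box);
      if (w != 0.0) { x[q] -= w * box; img[q] += (int)w; }
    }
    // neighbor refresh + force
    if (max_disp2(x, nl, n, box) > 0.25 * skin * skin)
      build_neighbors(x, n, box, p, ty, ex, skin, nl);
    e = compute_forces(x, n, box, p, ty, bonds, angles, nl, f);
    cap_forces();
    // B
    for (int a = 0; a < n; ++a) {
      double hm = 0.5 * dt / mass[a];
      v[3 * a] += hm * f[3 * a];
      v[3 * a + 1] += hm * f[3 * a + 1];
      v[3 * a + 2] += hm * f[3 * a + 2];
    }
    for (int q = 0; q < 3 * n; ++q)
      if (!std::isfinite(x[q]))
        stop("non-finite coordinate at step %d (overlap or unstable timestep)", s);
    if (s % cadence == 0) record(slot++, step0 + s);
  }

  NumericMatrix vout(n, 3);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) vout(a, d) = v[3 * a + d];
  return List::create(_["frames_pos"] = frames_pos,
                      _["frames_img"] = frames_img,
                      _["frame_step"] = frame_step,
                      _["energy_log"] = elog,
                      _["velocities"] = vout,
                      _["final_step"] = step0 + nsteps);
}
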