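// Langevin dynamics core for the four-component condensate model.
//
// All lengths are in units of the bead diameter sigma, energies in kBT.
// Pair interactions are 12-6 Lennard-Jones, cut AND shifted so the energy is
// continuous at the cutoff (forces are unaffected by the shift):
//   attractive pairs:      cutoff rc_attr (2.5 by default)
//   excluded-volume pairs: epsilon = 1, cutoff 2^(1/6) (WCA)
// Bonds are harmonic V = ks (r - 1)^2; angles V = k_bend (1 + cos theta)
// (zero for a straight triple); the confining wall is a purely repulsive
// shifted LJ acting on the gap Rc - |r|.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <functional>
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double CAP_FLOOR = 0.3;  // pair distances below this are capped

struct PairTerms {
  double e;      // energy
  double fr;     // force / r : F_i += fr * (x_i - x_j)
  bool capped;
};

// LJ with cut-and-shift. eps in kBT, rc the cutoff, r2 the squared distance.
static inline PairTerms lj_terms(double r2, double eps, double rc) {
  PairTerms out{0.0, 0.0, false};
  double rc2 = rc * rc;
  if (r2 >= rc2) return out;
  if (r2 < CAP_FLOOR * CAP_FLOOR) {
    r2 = CAP_FLOOR * CAP_FLOOR;
    out.capped = true;
  }
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  double inv12 = inv6 * inv6;
  double invc6 = 1.0 / (rc2 * rc2 * rc2);
  double shift = 4.0 * eps * (invc6 * invc6 - invc6);
  out.e = 4.0 * eps * (inv12 - inv6) - shift;
  out.fr = 24.0 * eps * (2.0 * inv12 - inv6) * inv2;
  return out;
}

struct ForceField {
  int n;
  std::vector<int> species;             // 0-based species codes
  std::vector<double> eps;              // ns x ns attraction strengths
  std::vector<int> attractive;          // ns x ns 0/1 pair mode
  int ns;
  std::vector<std::pair<int, int> > bonds;    // 0-based
  std::vector<std::array<int, 3> > angles;    // 0-based, centre second
  std::unordered_set<int64_t> excluded;       // bonded (1-2) pairs
  double Rc, ks, kBend, rcAttr;
  double rcRep;

  long cappedCount = 0;

  ForceField(int n_, const IntegerVector& spec, const IntegerMatrix& bondM,
             const IntegerMatrix& angleM, const NumericMatrix& epsM,
             const IntegerMatrix& attrM, double Rc_, double ks_, double kBend_,
             double rcAttr_)
      : n(n_), ns(epsM.nrow()), Rc(Rc_), ks(ks_), kBend(kBend_),
        rcAttr(rcAttr_), rcRep(std::pow(2.0, 1.0 / 6.0)) {
    species.assign(spec.begin(), spec.end());
    eps.resize(ns * ns);
    attractive.resize(ns * ns);
    for (int a = 0; a < ns; ++a)
      for (int b = 0; b < ns; ++b) {
        eps[a * ns + b] = epsM(a, b);
        attractive[a * ns + b] = attrM(a, b);
      }
    for (int k = 0; k < bondM.nrow(); ++k) {
      int i = bondM(k, 0) - 1, j = bondM(k, 1) - 1;
      bonds.push_back({i, j});
      excluded.insert(pairKey(i, j));
    }
    for (int k = 0; k < angleM.nrow(); ++k)
      angles.push_back({angleM(k, 0) - 1, angleM(k, 1) - 1, angleM(k, 2) - 1});
  }

  int64_t pairKey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return static_cast<int64_t>(i) * n + j;
  }

  double pairCutoff(int si, int sj) const {
    return attractive[si * ns + sj] ? rcAttr : rcRep;
  }

  double pairEps(int si, int sj) const {
    return attractive[si * ns + sj] ? eps[si * ns + sj] : 1.0;
  }

  // adds the pair term (i, j); returns its energy
  inline double addPair(const std::vector<double>& x, std::vector<double>& f,
                        int i, int j) {
    if (excluded.count(pairKey(i, j))) return 0.0;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    int si = species[i], sj = species[j];
    double rc = pairCutoff(si, sj);
    if (r2 >= rc * rc) return 0.0;
    PairTerms t = lj_terms(r2, pairEps(si, sj), rc);
    if (t.capped) ++cappedCount;
    f[3 * i] += t.fr * dx;
    f[3 * i + 1] += t.fr * dy;
    f[3 * i + 2] += t.fr * dz;
    f[3 * j] -= t.fr * dx;
    f[3 * j + 1] -= t.fr * dy;
    f[3 * j + 2] -= t.fr * dz;
    return t.e;
  }

  double bondedEnergyForces(const std::vector<double>& x,
                            std::vector<double>& f) {
    double e = 0.0;
    for (auto& b : bonds) {
      int i = b.first, j = b.second;
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double dr = r - 1.0;
      e += ks * dr * dr;
      double fr = -2.0 * ks * dr / r;
      f[3 * i] += fr * dx;
      f[3 * i + 1] += fr * dy;
      f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx;
      f[3 * j + 1] -= fr * dy;
      f[3 * j + 2] -= fr * dz;
    }
    for (auto& a : angles) {
      int i = a[0], j = a[1], k = a[2];
      double ax = x[3 * i] - x[3 * j], ay = x[3 * i + 1] - x[3 * j + 1],
             az = x[3 * i + 2] - x[3 * j + 2];
      double bx = x[3 * k] - x[3 * j], by = x[3 * k + 1] - x[3 * j + 1],
             bz = x[3 * k + 2] - x[3 * j + 2];
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12) continue;
      double c = (ax * bx + ay * by + az * bz) / (la * lb);
      c = std::max(-1.0, std::min(1.0, c));
      e += kBend * (1.0 + c);
      // dV/dcos = kBend; F = -kBend * d(cos)/dx
      double inva = 1.0 / la, invb = 1.0 / lb;
      double fx_i = -kBend * (bx * inva * invb - c * ax * inva * inva);
      double fy_i = -kBend * (by * inva * invb - c * ay * inva * inva);
      double fz_i = -kBend * (bz * inva * invb - c * az * inva * inva);
      double fx_k = -kBend * (ax * inva * invb - c * bx * invb * invb);
      double fy_k = -kBend * (ay * inva * invb - c * by * invb * invb);
      double fz_k = -kBend * (az * inva * invb - c * bz * invb * invb);
      f[3 * i] += fx_i;
      f[3 * i + 1] += fy_i;
      f[3 * i + 2] += fz_i;
      f[3 * k] += fx_k;
      f[3 * k + 1] += fy_k;
      f[3 * k + 2] += fz_k;
      f[3 * j] -= fx_i + fx_k;
      f[3 * j + 1] -= fy_i + fy_k;
      f[3 * j + 2] -= fz_i + fz_k;
    }
    return e;
  }

  double wallEnergyForces(const std::vector<double>& x,
                          std::vector<double>& f) {
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      double rx = x[3 * i], ry = x[3 * i + 1], rz = x[3 * i + 2];
      double r = std::sqrt(rx * rx + ry * ry + rz * rz);
      double gap = Rc - r;
      if (gap >= rcRep) continue;
      if (gap < CAP_FLOOR) {
        gap = CAP_FLOOR;
        ++cappedCount;
      }
      double inv2 = 1.0 / (gap * gap);
      double inv6 = inv2 * inv2 * inv2;
      double inv12 = inv6 * inv6;
      e += 4.0 * (inv12 - inv6) + 1.0;
      // dV/dgap < 0 inside the cutoff; force on the bead is dV/dgap * rhat
      double dVdgap = (24.0 * inv6 - 48.0 * inv12) / gap;
      if (r > 1e-12) {
        double s = dVdgap / r;
        f[3 * i] += s * rx;
        f[3 * i + 1] += s * ry;
        f[3 * i + 2] += s * rz;
      }
    }
    return e;
  }
};

// ---- neighbour list ------------------------------------------------------

struct NeighborList {
  double rl;  // list cutoff = rc_attr + skin
  double skin;
  std::vector<std::pair<int, int> > pairs;
  std::vector<double> xRef;
  long rebuilds = 0;

  void build(const std::vector<double>& x, int n, double Rc) {
    pairs.clear();
    xRef = x;
    ++rebuilds;
    double box = 2.0 * Rc + 2.0;
    int nc = std::max(1, static_cast<int>(std::floor(box / rl)));
    // cap the grid so memory stays O(n) even in huge dilute boxes
    int ncCap = std::max(1, static_cast<int>(std::ceil(std::cbrt(4.0 * n + 8.0))));
    nc = std::min(nc, ncCap);
    double cell = box / nc;
    double origin = -Rc - 1.0;
    std::vector<std::vector<int> > cells(static_cast<size_t>(nc) * nc * nc);
    auto cellIndex = [&](double v) {
      int c = static_cast<int>((v - origin) / cell);
      return std::max(0, std::min(nc - 1, c));
    };
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      ci[i] = cellIndex(x[3 * i]);
      cj[i] = cellIndex(x[3 * i + 1]);
      ck[i] = cellIndex(x[3 * i + 2]);
      cells[(static_cast<size_t>(ci[i]) * nc + cj[i]) * nc + ck[i]].push_back(i);
    }
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i) {
      for (int a = std::max(0, ci[i] - 1); a <= std::min(nc - 1, ci[i] + 1); ++a)
        for (int b = std::max(0, cj[i] - 1); b <= std::min(nc - 1, cj[i] + 1); ++b)
          for (int c = std::max(0, ck[i] - 1); c <= std::min(nc - 1, ck[i] + 1);
               ++c) {
            for (int j : cells[(static_cast<size_t>(a) * nc + b) * nc + c]) {
              if (j <= i) continue;
              double dx = x[3 * i] - x[3 * j];
              double dy = x[3 * i + 1] - x[3 * j + 1];
              double dz = x[3 * i + 2] - x[3 * j + 2];
              if (dx * dx + dy * dy + dz * dz < rl2)
                pairs.push_back({i, j});
            }
          }
    }
  }

  bool stale(const std::vector<double>& x, int n) const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - xRef[3 * i];
      double dy = x[3 * i + 1] - xRef[3 * i + 1];
      double dz = x[3 * i + 2] - xRef[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

static double totalForces(ForceField& ff, NeighborList& nl,
                          const std::vector<double>& x,
                          std::vector<double>& f, bool useList) {
  std::fill(f.begin(), f.end(), 0.0);
  double pe = 0.0;
  if (useList) {
    if (nl.stale(x, ff.n)) nl.build(x, ff.n, ff.Rc);
    for (auto& p : nl.pairs) pe += ff.addPair(x, f, p.first, p.second);
  } else {
    for (int i = 0; i < ff.n; ++i)
      for (int j = i + 1; j < ff.n; ++j) pe += ff.addPair(x, f, i, j);
  }
  pe += ff.bondedEnergyForces(x, f);
  pe += ff.wallEnergyForces(x, f);
  return pe;
}

static void capForces(std::vector<double>& f, int n, double fcap) {
  if (fcap <= 0) return;
  for (int i = 0; i < n; ++i) {
    double fx = f[3 * i], fy = f[3 * i + 1], fz = f[3 * i + 2];
    double m = std::sqrt(fx * fx + fy * fy + fz * fz);
    if (m > fcap) {
      double s = fcap / m;
      f[3 * i] *= s;
      f[3 * i + 1] *= s;
      f[3 * i + 2] *= s;
    }
  }
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix pos, IntegerVector species,
                        IntegerMatrix bonds, IntegerMatrix angles,
                        NumericMatrix eps, IntegerMatrix attractive, double Rc,
                        double ks, double kBend, double rcAttr,
                        bool brute = false, double skin = 0.4) {
  int n = pos.nrow();
  ForceField ff(n, species, bonds, angles, eps, attractive, Rc, ks, kBend,
                rcAttr);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  NeighborList nl;
  nl.rl = rcAttr + skin;
  nl.skin = skin;
  if (!brute) nl.build(x, n, Rc);
  double pe = totalForces(ff, nl, x, f, !brute);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = f[3 * i + d];
  return List::create(_["forces"] = out, _["potential"] = pe,
                      _["capped"] = static_cast<double>(ff.cappedCount));
}

// BAOAB Langevin integrator. Friction enters as gamma * mass so the
// long-time diffusion coefficient of a free bead is kBT / (gamma * mass).
// [[Rcpp::export]]
List integrate_cpp(NumericMatrix pos, IntegerVector species,
                   IntegerMatrix bonds, IntegerMatrix angles,
                   NumericMatrix eps, IntegerMatrix attractive, double Rc,
                   double ks, double kBend, double rcAttr, double dt,
                   double gamma, double mass, double kBT, int nSteps,
                   int frameInterval, int seed, double forceCap = -1.0,
                   double skin = 0.4, double t0 = 0.0) {
  int n = pos.nrow();
  ForceField ff(n, species, bonds, angles, eps, attractive, Rc, ks, kBend,
                rcAttr);
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> normal(0.0, 1.0);

  // Maxwell-Boltzmann start so the kinetic temperature is correct from step 0
  double vs = std::sqrt(kBT / mass);
  if (kBT > 0)
    for (int i = 0; i < 3 * n; ++i) v[i] = vs * normal(rng);

  NeighborList nl;
  nl.rl = rcAttr + skin;
  nl.skin = skin;
  nl.build(x, n, Rc);

  double pe = totalForces(ff, nl, x, f, true);
  capForces(f, n, forceCap);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kBT / mass);
  double hdt = 0.5 * dt;

  if (frameInterval <= 0) frameInterval = std::max(1, nSteps);
  int nFrames = (nSteps > 0) ? nSteps / frameInterval : 0;
  List frames(nFrames + 1);
  NumericVector times(nFrames + 1), keTemp(nFrames + 1), peOut(nFrames + 1);

  auto snapshot = [&](int slot, int step) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fr(i, d) = x[3 * i + d];
    frames[slot] = fr;
    times[slot] = t0 + step * dt;
    double ke = 0.0;
    for (int i = 0; i < 3 * n; ++i) ke += 0.5 * mass * v[i] * v[i];
    keTemp[slot] = (n > 0) ? 2.0 * ke / (3.0 * n) : 0.0;
    peOut[slot] = pe;
  };
  snapshot(0, 0);

  int slot = 1;
  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += hdt * f[i] / mass;
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    if (gamma > 0 && kBT >= 0)
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * normal(rng);
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    pe = totalForces(ff, nl, x, f, true);
    capForces(f, n, forceCap);
    for (int i = 0; i < 3 * n; ++i) v[i] += hdt * f[i] / mass;

    if (step % frameInterval == 0 && slot <= nFrames) {
      if (!std::isfinite(pe))
        stop("non-finite potential energy at step %d; aborting run", step);
      snapshot(slot, step);
      ++slot;
    }
  }

  return List::create(
      _["frames"] = frames, _["times"] = times, _["kineticTemp"] = keTemp,
      _["potential"] = peOut, _["capped"] = static_cast<double>(ff.cappedCount),
      _["rebuilds"] = static_cast<double>(nl.rebuilds));
}

// ---- initial configuration ----------------------------------------------

// Confined self-avoiding random-walk growth for the polymer, uniform
// placement for free beads, then a deterministic pairwise push-off so no
// two beads sit closer than minDist.
// [[Rcpp::export]]
NumericMatrix init_positions_cpp(int nPolymer, int nFree, double Rc, int seed,
                                 double minDist = 0.8, double rExcl = 0.0) {
  int n = nPolymer + nFree;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9E3779B9ULL);
  std::normal_distribution<double> normal(0.0, 1.0);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  double rmax = Rc - 1.0;
  if (rmax <= 0) stop("confinement radius too small");

  std::vector<double> x;
  x.reserve(3 * n);

  auto randInSphere = [&](double& px, double& py, double& pz) {
    double r2;
    do {
      px = unif(rng) * rmax;
      py = unif(rng) * rmax;
      pz = unif(rng) * rmax;
      r2 = px * px + py * py + pz * pz;
    } while (r2 > rmax * rmax || r2 < rExcl * rExcl);
  };
  auto randDir = [&](double& dx, double& dy, double& dz) {
    double m;
    do {
      dx = normal(rng);
      dy = normal(rng);
      dz = normal(rng);
      m = std::sqrt(dx * dx + dy * dy + dz * dz);
    } while (m < 1e-8);
    dx /= m;
    dy /= m;
    dz /= m;
  };

  // occupancy grid, cell edge 1.0
  double origin = -Rc - 1.0;
  int nc = static_cast<int>(std::ceil((2.0 * Rc + 2.0)));
  std::vector<std::vector<int> > grid(static_cast<size_t>(nc) * nc * nc);
  auto cellOf = [&](double v) {
    int c = static_cast<int>(v - origin);
    return std::max(0, std::min(nc - 1, c));
  };
  auto gridKey = [&](double px, double py, double pz) {
    return (static_cast<size_t>(cellOf(px)) * nc + cellOf(py)) * nc + cellOf(pz);
  };
  double md2 = minDist * minDist;
  auto tooClose = [&](double px, double py, double pz, int upto) {
    int ca = cellOf(px), cb = cellOf(py), cc = cellOf(pz);
    for (int a = std::max(0, ca - 1); a <= std::min(nc - 1, ca + 1); ++a)
      for (int b = std::max(0, cb - 1); b <= std::min(nc - 1, cb + 1); ++b)
        for (int c = std::max(0, cc - 1); c <= std::min(nc - 1, cc + 1); ++c)
          for (int j : grid[(static_cast<size_t>(a) * nc + b) * nc + c]) {
            if (j >= upto) continue;
            double dx = px - x[3 * j], dy = py - x[3 * j + 1],
                   dz = pz - x[3 * j + 2];
            if (dx * dx + dy * dy + dz * dz < md2) return true;
          }
    return false;
  };
  auto push = [&](double px, double py, double pz) {
    x.push_back(px);
    x.push_back(py);
    x.push_back(pz);
    grid[gridKey(px, py, pz)].push_back(static_cast<int>(x.size() / 3) - 1);
  };

  // polymer growth with limited backtracking
  if (nPolymer > 0) {
    double px, py, pz;
    randInSphere(px, py, pz);
    push(px, py, pz);
    long backtracks = 0;
    while (static_cast<int>(x.size() / 3) < nPolymer) {
      int i = static_cast<int>(x.size() / 3);
      double lx = x[3 * (i - 1)], ly = x[3 * (i - 1) + 1],
             lz = x[3 * (i - 1) + 2];
      bool placed = false;
      for (int attempt = 0; attempt < 60; ++attempt) {
        double dx, dy, dz;
        randDir(dx, dy, dz);
        double cx = lx + dx, cy = ly + dy, cz = lz + dz;
        double cr2 = cx * cx + cy * cy + cz * cz;
        if (cr2 > rmax * rmax || cr2 < rExcl * rExcl) continue;
        if (tooClose(cx, cy, cz, i - 1)) continue;  // allow contact with prev
        push(cx, cy, cz);
        placed = true;
        break;
      }
      if (!placed) {
        // drop the last bead and retry from one earlier
        if (i <= 1 || ++backtracks > 50L * nPolymer)
          stop("polymer placement infeasible: %d of %d beads placed", i,
               nPolymer);
        int last = i - 1;
        auto& cell = grid[gridKey(x[3 * last], x[3 * last + 1], x[3 * last + 2])];
        cell.erase(std::remove(cell.begin(), cell.end(), last), cell.end());
        x.resize(3 * last);
      }
    }
  }

  for (int k = 0; k < nFree; ++k) {
    double px, py, pz;
    bool ok = false;
    for (int attempt = 0; attempt < 400; ++attempt) {
      randInSphere(px, py, pz);
      if (!tooClose(px, py, pz, static_cast<int>(x.size() / 3) + 1)) {
        ok = true;
        break;
      }
    }
    if (!ok) randInSphere(px, py, pz);  // push-off below will separate
    push(px, py, pz);
  }

  // deterministic pairwise push-off
  for (int iter = 0; iter < 400; ++iter) {
    bool any = false;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= md2) continue;
        any = true;
        double r = std::sqrt(r2);
        double ux, uy, uz;
        if (r < 1e-9) {
          randDir(ux, uy, uz);
        } else {
          ux = dx / r;
          uy = dy / r;
          uz = dz / r;
        }
        double s = 0.5 * (minDist - r) + 1e-6;
        x[3 * i] += s * ux;
        x[3 * i + 1] += s * uy;
        x[3 * i + 2] += s * uz;
        x[3 * j] -= s * ux;
        x[3 * j + 1] -= s * uy;
        x[3 * j + 2] -= s * uz;
        for (int b : {i, j}) {
          double m = std::sqrt(x[3 * b] * x[3 * b] + x[3 * b + 1] * x[3 * b + 1] +
                               x[3 * b + 2] * x[3 * b + 2]);
          if (m > rmax) {
            double sc = rmax / m;
            x[3 * b] *= sc;
            x[3 * b + 1] *= sc;
            x[3 * b + 2] *= sc;
          }
        }
      }
    if (!any) break;
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}

// Minimum pairwise distance (brute force); used by tests and the initializer
// contract.
// [[Rcpp::export]]
double min_pair_distance_cpp(NumericMatrix pos) {
  int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// Single-linkage clustering of points within `cutoff` (grid-accelerated
// union-find). Returns 1-based labels renumbered by lowest member index.
// [[Rcpp::export]]
IntegerVector cluster_labels_cpp(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  IntegerVector labels(n);
  if (n == 0) return labels;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  auto unite = [&](int i, int j) {
    int ri = find(i), rj = find(j);
    if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
  };

  double minx = pos(0, 0), miny = pos(0, 1), minz = pos(0, 2);
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, pos(i, 0));
    miny = std::min(miny, pos(i, 1));
    minz = std::min(minz, pos(i, 2));
  }
  double cell = std::max(cutoff, 1e-9);
  auto key = [&](int i, int d) {
    double v = (d == 0 ? pos(i, 0) - minx : d == 1 ? pos(i, 1) - miny
                                                   : pos(i, 2) - minz);
    return static_cast<long>(v / cell);
  };
  std::unordered_map<int64_t, std::vector<int> > grid;
  auto hash = [](long a, long b, long c) {
    return (static_cast<int64_t>(a) * 73856093LL) ^
           (static_cast<int64_t>(b) * 19349663LL) ^
           (static_cast<int64_t>(c) * 83492791LL);
  };
  for (int i = 0; i < n; ++i)
    grid[hash(key(i, 0), key(i, 1), key(i, 2))].push_back(i);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    long a = key(i, 0), b = key(i, 1), c = key(i, 2);
    for (long da = -1; da <= 1; ++da)
      for (long db = -1; db <= 1; ++db)
        for (long dc = -1; dc <= 1; ++dc) {
          auto it = grid.find(hash(a + da, b + db, c + dc));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double dx = pos(i, 0) - pos(j, 0);
            double dy = pos(i, 1) - pos(j, 1);
            double dz = pos(i, 2) - pos(j, 2);
            if (dx * dx + dy * dy + dz * dz <= c2) unite(i, j);
          }
        }
  }
  // renumber roots by lowest member index (root IS the lowest member here)
  std::unordered_map<int, int> lab;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (!lab.count(r)) lab[r] = ++next;
    labels[i] = lab[r];
  }
  return labels;
}
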