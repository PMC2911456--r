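// Numeric kernels for the spatial engine: neighbor search, force evaluation
// and the Langevin velocity-Verlet step. All randomness goes through R's RNG
// so that set.seed() makes whole simulations reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
#include <algorithm>
using namespace Rcpp;

static inline double wrap_delta(double dx, double box, bool periodic) {
  if (periodic) dx -= box * std::round(dx / box);
  return dx;
}

// Squared minimum-image distance between rows a and b of pos.
static inline double dist2_mi(const NumericMatrix &pos, int a, int b,
                              const NumericVector &box, const LogicalVector &per,
                              double *dvec) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double dx = wrap_delta(pos(b, k) - pos(a, k), box[k], per[k]);
    dvec[k] = dx;
    s += dx * dx;
  }
  return s;
}

struct CellGrid {
  int nc[3];
  double clen[3];
  std::vector<std::vector<int>> cells;
  bool ok;
};

static void build_grid(const NumericMatrix &pos, const NumericVector &box,
                       const LogicalVector &per, double cutoff, CellGrid &g) {
  g.ok = true;
  for (int k = 0; k < 3; ++k) {
    g.nc[k] = std::max(1, (int)std::floor(box[k] / cutoff));
    if (per[k] && g.nc[k] < 3) { g.ok = false; return; }
    g.clen[k] = box[k] / g.nc[k];
  }
  int ntot = g.nc[0] * g.nc[1] * g.nc[2];
  if (ntot > 2000000) { g.ok = false; return; }
  g.cells.assign(ntot, std::vector<int>());
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    int idx[3];
    for (int k = 0; k < 3; ++k) {
      double x = pos(i, k);
      if (per[k]) {
        x -= box[k] * std::floor(x / box[k]);
      } else {
        if (x < 0) x = 0;
        if (x >= box[k]) x = box[k] * (1.0 - 1e-12);
      }
      int c = (int)(x / g.clen[k]);
      if (c >= g.nc[k]) c = g.nc[k] - 1;
      if (c < 0) c = 0;
      idx[k] = c;
    }
    g.cells[(idx[2] * g.nc[1] + idx[1]) * g.nc[0] + idx[0]].push_back(i);
  }
}

// Enumerate unordered pairs with separation <= cutoff, calling fn(i, j, r, dvec)
// where dvec points from i to j (minimum image).
template <typename F>
static void for_pairs(const NumericMatrix &pos, const NumericVector &box,
                      const LogicalVector &per, double cutoff, F fn) {
  int n = pos.nrow();
  double dvec[3];
  double cut2 = cutoff * cutoff;
  CellGrid g;
  build_grid(pos, box, per, cutoff, g);
  if (!g.ok) { // brute force fallback (small boxes / tiny systems)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d2 = dist2_mi(pos, i, j, box, per, dvec);
        if (d2 <= cut2) fn(i, j, std::sqrt(d2), dvec);
      }
    return;
  }
  // half-neighborhood stencil
  for (int cz = 0; cz < g.nc[2]; ++cz)
    for (int cy = 0; cy < g.nc[1]; ++cy)
      for (int cx = 0; cx < g.nc[0]; ++cx) {
        const std::vector<int> &home = g.cells[(cz * g.nc[1] + cy) * g.nc[0] + cx];
        if (home.empty()) continue;
        for (int sz = -1; sz <= 1; ++sz)
          for (int sy = -1; sy <= 1; ++sy)
            for (int sx = -1; sx <= 1; ++sx) {
              // visit each unordered cell pair once
              if (sz < 0) continue;
              if (sz == 0 && sy < 0) continue;
              if (sz == 0 && sy == 0 && sx < 0) continue;
              int ox = cx + sx, oy = cy + sy, oz = cz + sz;
              if (per[0]) ox = (ox + g.nc[0]) % g.nc[0]; else if (ox < 0 || ox >= g.nc[0]) continue;
              if (per[1]) oy = (oy + g.nc[1]) % g.nc[1]; else if (oy < 0 || oy >= g.nc[1]) continue;
              if (per[2]) oz = (oz + g.nc[2]) % g.nc[2]; else if (oz < 0 || oz >= g.nc[2]) continue;
              const std::vector<int> &other = g.cells[(oz * g.nc[1] + oy) * g.nc[0] + ox];
              bool same = (sx == 0 && sy == 0 && sz == 0);
              if (same) {
                for (size_t a = 0; a < home.size(); ++a)
                  for (size_t b = a + 1; b < home.size(); ++b) {
                    double d2 = dist2_mi(pos, home[a], home[b], box, per, dvec);
                    if (d2 <= cut2) fn(home[a], home[b], std::sqrt(d2), dvec);
                  }
              } else {
                for (size_t a = 0; a < home.size(); ++a)
                  for (size_t b = 0; b < other.size(); ++b) {
                    double d2 = dist2_mi(pos, home[a], other[b], box, per, dvec);
                    if (d2 <= cut2) fn(home[a], other[b], std::sqrt(d2), dvec);
                  }
              }
            }
      }
}

// [[Rcpp::export]]
List pairs_within_cpp(NumericMatrix pos, NumericVector box, LogicalVector periodic,
                      double cutoff) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for_pairs(pos, box, periodic, cutoff,
            [&](int i, int j, double r, const double *) {
              ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(r);
            });
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["dist"] = wrap(dd));
}

// Configurational forces: harmonic bonds E = Kd (d - d0)^2, harmonic angles
// E = Ka (a - a0)^2 (center j), and soft-sphere repulsion
// E = A (1 + cos(pi r / rc)) for r < rc with rc = r_i + r_j.
// Pair repulsion and bonded terms lying entirely inside one rigid group are
// skipped (rigid[i] > 0 marks membership).
static double conf_forces(const NumericMatrix &pos, NumericMatrix &f,
                          const IntegerMatrix &bonds, const NumericVector &bond_d0,
                          double Kd,
                          const IntegerMatrix &angles, const NumericVector &angle_a0,
                          double Ka,
                          const NumericVector &radius, double Arep,
                          const NumericVector &box, const LogicalVector &per,
                          const IntegerVector &rigid) {
  int n = pos.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  double energy = 0.0;
  double dvec[3];
  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    if (rigid[i] > 0 && rigid[i] == rigid[j]) continue;
    double d2 = dist2_mi(pos, i, j, box, per, dvec);
    double d = std::sqrt(d2);
    if (d < 1e-12) continue;
    double dd = d - bond_d0[b];
    energy += Kd * dd * dd;
    double fmag = -2.0 * Kd * dd; // along +dvec acting on j
    for (int k = 0; k < 3; ++k) {
      double fk = fmag * dvec[k] / d;
      f(j, k) += fk;
      f(i, k) -= fk;
    }
  }
  // angles (center is column 2, i.e. triple (i, j, k) with vertex j)
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    if (rigid[i] > 0 && rigid[i] == rigid[j] && rigid[i] == rigid[k]) continue;
    double rij[3], rkj[3];
    double dij2 = 0, dkj2 = 0;
    for (int m = 0; m < 3; ++m) {
      rij[m] = wrap_delta(pos(i, m) - pos(j, m), box[m], per[m]);
      rkj[m] = wrap_delta(pos(k, m) - pos(j, m), box[m], per[m]);
      dij2 += rij[m] * rij[m];
      dkj2 += rkj[m] * rkj[m];
    }
    double dij = std::sqrt(dij2), dkj = std::sqrt(dkj2);
    if (dij < 1e-9 || dkj < 1e-9) continue;
    double cosv = 0;
    for (int m = 0; m < 3; ++m) cosv += rij[m] * rkj[m];
    cosv /= (dij * dkj);
    if (cosv > 1.0) cosv = 1.0;
    if (cosv < -1.0) cosv = -1.0;
    double theta = std::acos(cosv);
    double sinv = std::sqrt(1.0 - cosv * cosv);
    if (sinv < 1e-4) sinv = 1e-4; // bounded force at collinear configurations
    double dtheta = theta - angle_a0[a];
    energy += Ka * dtheta * dtheta;
    // f = -dE/dtheta * dtheta/dx; dtheta/dcos = -1/sin flips the sign
    double coef = 2.0 * Ka * dtheta / sinv;
    for (int m = 0; m < 3; ++m) {
      double fi = coef * (rkj[m] / dkj - cosv * rij[m] / dij) / dij;
      double fk = coef * (rij[m] / dij - cosv * rkj[m] / dkj) / dkj;
      f(i, m) += fi;
      f(k, m) += fk;
      f(j, m) -= fi + fk;
    }
  }
  // soft-sphere repulsion
  if (Arep > 0.0 && n > 1) {
    double rmax = 0;
    for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
    double cutoff = 2.0 * rmax;
    if (cutoff > 0) {
      for_pairs(pos, box, per, cutoff, [&](int i, int j, double r, const double *dv) {
        if (rigid[i] > 0 && rigid[i] == rigid[j]) return;
        double rc = radius[i] + radius[j];
        if (r >= rc || rc <= 0) return;
        energy += Arep * (1.0 + std::cos(M_PI * r / rc));
        double fmag = Arep * M_PI / rc * std::sin(M_PI * r / rc); // repulsive
        if (r < 1e-9) return;
        for (int m = 0; m < 3; ++m) {
          double fk = fmag * dv[m] / r;
          f(j, m) += fk;  // dv points i -> j, push j away
          f(i, m) -= fk;
        }
      });
    }
  }
  return energy;
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix pos,
                        IntegerMatrix bonds, NumericVector bond_d0, double Kd,
                        IntegerMatrix angles, NumericVector angle_a0, double Ka,
                        NumericVector radius, double Arep,
                        NumericVector box, LogicalVector periodic,
                        IntegerVector rigid) {
  NumericMatrix f(pos.nrow(), 3);
  double e = conf_forces(pos, f, bonds, bond_d0, Kd, angles, angle_a0, Ka,
                         radius, Arep, box, periodic, rigid);
  return List::create(_["force"] = f, _["energy"] = e);
}

static void apply_boundary(NumericMatrix &pos, NumericMatrix &vel, int i,
                           const NumericVector &box, const LogicalVector &per) {
  for (int k = 0; k < 3; ++k) {
    double x = pos(i, k);
    if (per[k]) {
      pos(i, k) = x - box[k] * std::floor(x / box[k]);
    } else {
      // reflecting wall
      while (x < 0 || x > box[k]) {
        if (x < 0) { x = -x; vel(i, k) = -vel(i, k); }
        if (x > box[k]) { x = 2 * box[k] - x; vel(i, k) = -vel(i, k); }
      }
      pos(i, k) = x;
    }
  }
}

static void solve3(const double I[3][3], const double b[3], double w[3]) {
  // solve I w = b with a tiny regularisation (linear/point groups)
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = I[i][j];
  double tr = a[0][0] + a[1][1] + a[2][2];
  double eps = 1e-9 * (tr > 0 ? tr : 1.0);
  for (int i = 0; i < 3; ++i) a[i][i] += eps;
  double x[3] = {b[0], b[1], b[2]};
  // Gaussian elimination with partial pivoting
  int idx[3] = {0, 1, 2};
  for (int c = 0; c < 3; ++c) {
    int p = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(a[idx[r]][c]) > std::fabs(a[idx[p]][c])) p = r;
    std::swap(idx[c], idx[p]);
    double piv = a[idx[c]][c];
    for (int r = c + 1; r < 3; ++r) {
      double m = a[idx[r]][c] / piv;
      for (int cc = c; cc < 3; ++cc) a[idx[r]][cc] -= m * a[idx[c]][cc];
      x[idx[r]] -= m * x[idx[c]];
    }
  }
  for (int c = 2; c >= 0; --c) {
    double s = x[idx[c]];
    for (int cc = c + 1; cc < 3; ++cc) s -= a[idx[c]][cc] * w[cc];
    w[c] = s / a[idx[c]][c];
  }
}

static void rotate_about(double *v, const double *axis, double angle) {
  // Rodrigues rotation of v about unit axis
  double c = std::cos(angle), s = std::sin(angle);
  double dot = v[0] * axis[0] + v[1] * axis[1] + v[2] * axis[2];
  double cr[3] = {axis[1] * v[2] - axis[2] * v[1],
                  axis[2] * v[0] - axis[0] * v[2],
                  axis[0] * v[1] - axis[1] * v[0]};
  for (int k = 0; k < 3; ++k)
    v[k] = v[k] * c + cr[k] * s + axis[k] * dot * (1 - c);
}

// One (or several) Langevin velocity-Verlet steps. `force` holds the total
// force from the previous evaluation; the updated one is returned. Rigid
// groups translate/rotate as rigid bodies driven by the summed member forces
// (members of a group are never wrapped individually; the group is remapped
// by whole box lengths when its center leaves the box). Frozen particles
// never move.
// [[Rcpp::export]]
List md_step_cpp(NumericMatrix pos_in, NumericMatrix vel_in, NumericMatrix force,
                 NumericVector mass, NumericVector damp,
                 LogicalVector frozen, IntegerVector rigid,
                 IntegerMatrix bonds, NumericVector bond_d0, double Kd,
                 IntegerMatrix angles, NumericVector angle_a0, double Ka,
                 NumericVector radius, double Arep,
                 NumericVector box, LogicalVector periodic,
                 double dt, double Temp, int nsteps) {
  int n = pos_in.nrow();
  // work on copies: callers may hold references to the inputs
  NumericMatrix pos(clone(pos_in)), vel(clone(vel_in));
  NumericMatrix f(clone(force));
  NumericMatrix fc(n, 3);
  // rigid bookkeeping
  int ngroup = 0;
  for (int i = 0; i < n; ++i) ngroup = std::max(ngroup, rigid[i]);
  std::vector<std::vector<int>> groups(ngroup);
  for (int i = 0; i < n; ++i)
    if (rigid[i] > 0) groups[rigid[i] - 1].push_back(i);
  double energy = 0.0;
  bool nonfinite = false;

  for (int step = 0; step < nsteps && !nonfinite; ++step) {
    // --- first half kick + drift for free particles
    for (int i = 0; i < n; ++i) {
      if (frozen[i] || rigid[i] > 0) continue;
      for (int k = 0; k < 3; ++k) {
        vel(i, k) += 0.5 * dt * f(i, k) / mass[i];
        pos(i, k) += dt * vel(i, k);
      }
      apply_boundary(pos, vel, i, box, periodic);
    }
    // --- rigid groups: single full-step update using current forces
    for (int g = 0; g < ngroup; ++g) {
      const std::vector<int> &mem = groups[g];
      if (mem.empty()) continue;
      if (frozen[mem[0]]) continue;
      double M = 0, com[3] = {0, 0, 0}, V[3] = {0, 0, 0}, F[3] = {0, 0, 0};
      for (int idx : mem) {
        M += mass[idx];
        for (int k = 0; k < 3; ++k) {
          com[k] += mass[idx] * pos(idx, k);
          V[k] += mass[idx] * vel(idx, k);
          F[k] += f(idx, k);
        }
      }
      for (int k = 0; k < 3; ++k) { com[k] /= M; V[k] /= M; }
      double tau[3] = {0, 0, 0}, L[3] = {0, 0, 0};
      double I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int idx : mem) {
        double r[3], v[3], fi[3];
        for (int k = 0; k < 3; ++k) {
          r[k] = pos(idx, k) - com[k];
          v[k] = vel(idx, k) - V[k];
          fi[k] = f(idx, k);
        }
        tau[0] += r[1] * fi[2] - r[2] * fi[1];
        tau[1] += r[2] * fi[0] - r[0] * fi[2];
        tau[2] += r[0] * fi[1] - r[1] * fi[0];
        L[0] += mass[idx] * (r[1] * v[2] - r[2] * v[1]);
        L[1] += mass[idx] * (r[2] * v[0] - r[0] * v[2]);
        L[2] += mass[idx] * (r[0] * v[1] - r[1] * v[0]);
        double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            I[a][b] += mass[idx] * ((a == b ? r2 : 0.0) - r[a] * r[b]);
      }
      // translational update
      for (int k = 0; k < 3; ++k) {
        V[k] += dt * F[k] / M;
        com[k] += dt * V[k];
      }
      // rotational update
      for (int k = 0; k < 3; ++k) L[k] += dt * tau[k];
      double w[3];
      solve3(I, L, w);
      double wmag = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      double axis[3] = {0, 0, 1};
      double ang = wmag * dt;
      if (wmag > 1e-14) for (int k = 0; k < 3; ++k) axis[k] = w[k] / wmag;
      // move members: rotate body about new COM, then set rigid velocities
      double shift[3] = {0, 0, 0};
      for (int k = 0; k < 3; ++k) {
        if (periodic[k]) shift[k] = box[k] * std::floor(com[k] / box[k]);
      }
      for (int idx : mem) {
        double r[3];
        double oldcom[3];
        for (int k = 0; k < 3; ++k) {
          oldcom[k] = com[k] - dt * V[k];
          r[k] = pos(idx, k) - oldcom[k];
        }
        if (ang != 0.0) rotate_about(r, axis, ang);
        double wr[3] = {w[1] * r[2] - w[2] * r[1],
                        w[2] * r[0] - w[0] * r[2],
                        w[0] * r[1] - w[1] * r[0]};
        for (int k = 0; k < 3; ++k) {
          pos(idx, k) = com[k] + r[k] - shift[k];
          vel(idx, k) = V[k] + wr[k];
        }
      }
    }
    // --- forces at new positions
    energy = conf_forces(pos, fc, bonds, bond_d0, Kd, angles, angle_a0, Ka,
                         radius, Arep, box, periodic, rigid);
    // add Langevin friction + noise
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) { for (int k = 0; k < 3; ++k) fc(i, k) = 0; continue; }
      double g = (damp[i] > 0 && R_finite(damp[i])) ? mass[i] / damp[i] : 0.0;
      double sd = (g > 0 && Temp > 0) ? std::sqrt(2.0 * g * Temp / dt) : 0.0;
      for (int k = 0; k < 3; ++k) {
        double fr = (sd > 0) ? sd * norm_rand() : 0.0;
        fc(i, k) += -g * vel(i, k) + fr;
      }
    }
    // --- second half kick for free particles
    for (int i = 0; i < n; ++i) {
      if (frozen[i] || rigid[i] > 0) {
        for (int k = 0; k < 3; ++k) f(i, k) = fc(i, k);
        continue;
      }
      for (int k = 0; k < 3; ++k) {
        vel(i, k) += 0.5 * dt * fc(i, k) / mass[i];
        f(i, k) = fc(i, k);
      }
    }
    for (int i = 0; i < n && !nonfinite; ++i)
      for (int k = 0; k < 3; ++k)
        if (!R_finite(pos(i, k))) { nonfinite = true; break; }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["force"] = f,
                      _["energy"] = energy, _["ok"] = !nonfinite);
}

// ---- reaction-side helpers -------------------------------------------------

// Geometric compatibility of a candidate pair (1-based molecule/component
// indices). comp_d is an nspecies x maxcomp matrix of component lengths,
// alpha a list of per-species ideal-angle matrices (NaN where undefined).
// [[Rcpp::export]]
bool compat_cpp(NumericMatrix pos, IntegerMatrix bond_to,
                IntegerVector species, NumericMatrix comp_d,
                IntegerVector ncomp, NumericVector t_dist,
                NumericMatrix t_ang_comp,
                List alpha, NumericVector box, LogicalVector periodic,
                int i, int j, int ci, int cj) {
  int a = i - 1, b = j - 1;
  int spa = species[a] - 1, spb = species[b] - 1;
  double dvec[3];
  double d2 = 0;
  for (int k = 0; k < 3; ++k) {
    double dx = wrap_delta(pos(b, k) - pos(a, k), box[k], periodic[k]);
    dvec[k] = dx;
    d2 += dx * dx;
  }
  double dist = std::sqrt(d2);
  if (dist < 1e-9) return false; // degenerate overlap
  double d0 = comp_d(spa, ci - 1) + comp_d(spb, cj - 1);
  double tol = std::max(t_dist[spa], t_dist[spb]);
  if (std::fabs(dist - d0) > tol) return false;
  NumericMatrix al_a = alpha[spa], al_b = alpha[spb];
  for (int side = 0; side < 2; ++side) {
    int m = side == 0 ? a : b;
    int sp = side == 0 ? spa : spb;
    int cm = side == 0 ? ci - 1 : cj - 1;
    NumericMatrix &al = side == 0 ? al_a : al_b;
    double sgn = side == 0 ? 1.0 : -1.0;
    // tolerance of the reacting component of this molecule
    double ta = t_ang_comp(sp, cm);
    for (int c = 0; c < ncomp[sp]; ++c) {
      int q = bond_to(m, c);
      if (q == 0) continue;
      double ideal = al(c, cm);
      if (!R_finite(ideal)) continue;
      double bv[3];
      double n2 = 0, dot = 0;
      for (int k = 0; k < 3; ++k) {
        double dx = wrap_delta(pos(q - 1, k) - pos(m, k), box[k], periodic[k]);
        bv[k] = dx;
        n2 += dx * dx;
        dot += dx * sgn * dvec[k];
      }
      double nb = std::sqrt(n2);
      if (nb < 1e-9) return false;
      double cosv = dot / (nb * dist);
      if (cosv > 1.0) cosv = 1.0;
      if (cosv < -1.0) cosv = -1.0;
      if (std::fabs(std::acos(cosv) - ideal) > ta) return false;
    }
  }
  return true;
}

// Build the bond / angle term arrays for the force kernels from the
// per-component bond tables. Bonds internal to one rigid group are omitted;
// angle terms only when not all three members share a rigid group.
// [[Rcpp::export]]
List build_bonded_cpp(IntegerMatrix bond_to, IntegerMatrix bond_comp,
                      IntegerVector species, NumericMatrix comp_d,
                      IntegerVector ncomp, List alpha, IntegerVector rigid) {
  int n = bond_to.nrow();
  std::vector<int> bi, bj, ai, aj, ak;
  std::vector<double> bd, aa;
  std::vector<int> bonded;
  for (int m = 0; m < n; ++m) {
    int sp = species[m] - 1;
    NumericMatrix al = alpha[sp];
    bonded.clear();
    for (int c = 0; c < ncomp[sp]; ++c) {
      int p = bond_to(m, c);
      if (p == 0) continue;
      bonded.push_back(c);
      if (p - 1 > m && !(rigid[m] > 0 && rigid[m] == rigid[p - 1])) {
        bi.push_back(m + 1);
        bj.push_back(p);
        int pc = bond_comp(m, c);
        bd.push_back(comp_d(sp, c) + comp_d(species[p - 1] - 1, pc - 1));
      }
    }
    for (size_t x = 0; x + 1 < bonded.size(); ++x)
      for (size_t y = x + 1; y < bonded.size(); ++y) {
        double a0 = al(bonded[x], bonded[y]);
        if (!R_finite(a0)) continue;
        int p1 = bond_to(m, bonded[x]), p2 = bond_to(m, bonded[y]);
        if (rigid[m] > 0 && rigid[m] == rigid[p1 - 1] &&
            rigid[m] == rigid[p2 - 1]) continue;
        ai.push_back(p1);
        aj.push_back(m + 1);
        ak.push_back(p2);
        aa.push_back(a0);
      }
  }
  IntegerMatrix bonds(bi.size(), 2), angles(ai.size(), 3);
  for (size_t r = 0; r < bi.size(); ++r) { bonds(r, 0) = bi[r]; bonds(r, 1) = bj[r]; }
  for (size_t r = 0; r < ai.size(); ++r) {
    angles(r, 0) = ai[r]; angles(r, 1) = aj[r]; angles(r, 2) = ak[r];
  }
  return List::create(_["bonds"] = bonds, _["bond_d0"] = wrap(bd),
                      _["angles"] = angles, _["angle_a0"] = wrap(aa));
}

// Batched bimolecular reaction phase for "simple" rules (both reactant
// patterns single-node). Candidates are processed in random order; each is
// Bernoulli-drawn with its rule's firing probability, then checked for
// consumed participants, the refractory condition (binding), an injective
// acted-component assignment, and geometric compatibility. Firings consume
// their participants; because a firing only mutates its own (consumed)
// molecules, evaluating the whole batch against the step-start state is
// equivalent to interleaved execution. Returns the chosen firings in order.
// [[Rcpp::export]]
List bi_step_cpp(IntegerVector cand_i, IntegerVector cand_j, IntegerVector cand_rule,
                 NumericVector pfire, List ruleinfo, LogicalVector is_binding,
                 NumericMatrix pos, IntegerMatrix bond_to, IntegerMatrix state,
                 IntegerVector species, NumericMatrix comp_d, IntegerVector ncomp,
                 NumericVector t_dist, NumericMatrix t_ang_comp, List alpha,
                 NumericVector box, LogicalVector periodic,
                 NumericVector refract, double now, LogicalVector consumed_) {
  int nc = cand_i.size();
  LogicalVector consumed = clone(consumed_);
  std::vector<int> order(nc);
  for (int k = 0; k < nc; ++k) order[k] = k;
  // Fisher-Yates with R's RNG
  for (int k = nc - 1; k > 0; --k) {
    int r = (int)(unif_rand() * (k + 1));
    if (r > k) r = k;
    std::swap(order[k], order[r]);
  }
  std::vector<int> fi, fj, frule, fci, fcj;
  int rej_refr = 0, stale = 0;

  // enumerate acted-component options of a simple side
  auto side_options = [&](List side, int m, std::vector<int> &opts) {
    opts.clear();
    int nslots = as<int>(side["ncons"]);
    int acted = as<int>(side["acted"]) - 1;
    List cands = side["cands"];
    List state_req = side["state_req"];
    IntegerVector bond_req = side["bond_req"];
    auto slot_ok = [&](int s, int cc, IntegerVector &scands, IntegerVector &sreq) {
      for (int p = 0; p < scands.size(); ++p) {
        if (scands[p] != cc) continue;
        if (sreq[p] > 0 && state(m, cc - 1) != sreq[p]) return false;
        int bt = bond_to(m, cc - 1);
        if (bond_req[s] == 0 && bt != 0) return false;
        if (bond_req[s] == 1 && bt == 0) return false;
        return true;
      }
      return false;
    };
    IntegerVector acands = cands[acted];
    IntegerVector areq = state_req[acted];
    for (int p = 0; p < acands.size(); ++p) {
      int cc = acands[p];
      if (!slot_ok(acted, cc, acands, areq)) continue;
      // injectivity: the remaining slots must still be assignable
      bool ok = true;
      if (nslots > 1) {
        std::vector<int> used = {cc};
        std::function<bool(int)> rec = [&](int sidx) {
          if (sidx >= nslots) return true;
          if (sidx == acted) return rec(sidx + 1);
          IntegerVector scands = cands[sidx];
          IntegerVector sreq = state_req[sidx];
          for (int q = 0; q < scands.size(); ++q) {
            int c2 = scands[q];
            if (std::find(used.begin(), used.end(), c2) != used.end()) continue;
            if (!slot_ok(sidx, c2, scands, sreq)) continue;
            used.push_back(c2);
            if (rec(sidx + 1)) { used.pop_back(); return true; }
            used.pop_back();
          }
          return false;
        };
        ok = rec(0);
      }
      if (ok) opts.push_back(cc);
    }
  };

  std::vector<int> o1, o2;
  for (int kk = 0; kk < nc; ++kk) {
    int k = order[kk];
    if (unif_rand() >= pfire[k]) continue;
    int a = cand_i[k], b = cand_j[k];
    if (consumed[a - 1] || consumed[b - 1]) { ++stale; continue; }
    int ridx = cand_rule[k] - 1;
    if (is_binding[ridx] &&
        (refract[a - 1] > now || refract[b - 1] > now)) { ++rej_refr; continue; }
    List info = ruleinfo[ridx];
    side_options(info["side1"], a - 1, o1);
    if (o1.empty()) continue;
    side_options(info["side2"], b - 1, o2);
    if (o2.empty()) continue;
    // collect geometrically compatible combos, pick one at random
    std::vector<std::pair<int, int>> good;
    for (int x : o1) for (int y : o2) {
      if (compat_cpp(pos, bond_to, species, comp_d, ncomp, t_dist, t_ang_comp,
                     alpha, box, periodic, a, b, x, y))
        good.push_back({x, y});
    }
    if (good.empty()) continue;
    int pick = (int)(unif_rand() * good.size());
    if (pick >= (int)good.size()) pick = good.size() - 1;
    fi.push_back(a); fj.push_back(b); frule.push_back(ridx + 1);
    fci.push_back(good[pick].first); fcj.push_back(good[pick].second);
    consumed[a - 1] = true; consumed[b - 1] = true;
  }
  return List::create(_["i"] = wrap(fi), _["j"] = wrap(fj),
                      _["rule"] = wrap(frule), _["ci"] = wrap(fci),
                      _["cj"] = wrap(fcj), _["rej_refractory"] = rej_refr,
                      _["stale"] = stale);
}
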