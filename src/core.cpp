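#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Internal unit system: length A, mass g/mol, energy kcal/mol.
// Derived time unit tau = sqrt(g/mol * A^2 / (kcal/mol)) ~ 48.89 fs.
// All quantities entering these routines are already in internal units.

namespace {

struct FF {
  double eps;
  double sigma[2];   // 0 = protein, 1 = dna
  double lambda[2][2];
  double Kb, r0, Ktheta, theta0;
  double cutoff_factor;
  double sig_ij(int si, int sj) const { return 0.5 * (sigma[si] + sigma[sj]); }
};

FF parse_ff(const List& ffl) {
  FF ff;
  ff.eps = as<double>(ffl["epsilon"]);
  ff.sigma[0] = as<double>(ffl["sigma_P"]);
  ff.sigma[1] = as<double>(ffl["sigma_D"]);
  ff.lambda[0][0] = as<double>(ffl["lambda_PP"]);
  ff.lambda[0][1] = ff.lambda[1][0] = as<double>(ffl["lambda_PD"]);
  ff.lambda[1][1] = as<double>(ffl["lambda_DD"]);
  ff.Kb = as<double>(ffl["K_b"]);
  ff.r0 = as<double>(ffl["r0"]);
  ff.Ktheta = as<double>(ffl["K_theta"]);
  ff.theta0 = as<double>(ffl["theta0"]);
  ff.cutoff_factor = as<double>(ffl["cutoff_factor"]);
  return ff;
}

const double RMIN_FACTOR = 1.1224620483089301;  // 2^(1/6)

// Ashbaugh-Hatch pair energy; r2 = squared distance (pivot sampler path).
inline double ah_energy(double r2, double sig, double lam, double eps) {
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double ulj = 4.0 * eps * (s6 * s6 - s6);
  if (r2 <= RMIN_FACTOR * RMIN_FACTOR * sig * sig)
    return ulj + (1.0 - lam) * eps;
  return lam * ulj;
}

inline double min_image(double d, double box) {
  if (box <= 0.0) return d;
  d -= box * std::nearbyint(d / box);
  return d;
}

// ---- structure-of-arrays force engine -------------------------------------

typedef std::vector<std::vector<int> > ExclList;

struct Engine {
  int n;
  double box, invbox, hbox;
  double eps;
  // per species-pair tables
  double sig2[2][2], rc2[2][2], rmin2[2][2], lam[2][2];
  double max_cut;
  std::vector<int> sp;
  ExclList ex;               // directly bonded (1-2) exclusions
  std::vector<int> bond_i, bond_j;
  std::vector<int> ang_i, ang_j, ang_k;
  double Kb, r0, Ktheta, theta0;
  // cell list scratch
  std::vector<int> head, nxt;

  void init(const FF& ff, const IntegerVector& species, double box_edge,
            const IntegerMatrix& bonds, const IntegerMatrix& angles) {
    n = species.size();
    box = box_edge;
    invbox = 1.0 / box_edge;
    hbox = 0.5 * box_edge;
    eps = ff.eps;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        double s = ff.sig_ij(a, b);
        sig2[a][b] = s * s;
        rc2[a][b] = ff.cutoff_factor * s * ff.cutoff_factor * s;
        rmin2[a][b] = RMIN_FACTOR * RMIN_FACTOR * s * s;
        lam[a][b] = ff.lambda[a][b];
      }
    bool hasP = false, hasD = false;
    for (int i = 0; i < n; ++i) { if (species[i] == 0) hasP = true; else hasD = true; }
    double s = 0.0;
    if (hasP) s = std::max(s, ff.sigma[0]);
    if (hasD) s = std::max(s, ff.sigma[1]);
    if (hasP && hasD) s = std::max(s, ff.sig_ij(0, 1));
    max_cut = ff.cutoff_factor * s;
    sp.assign(species.begin(), species.end());
    ex.assign(n, std::vector<int>());
    for (int b = 0; b < bonds.nrow(); ++b) {
      bond_i.push_back(bonds(b, 0));
      bond_j.push_back(bonds(b, 1));
      ex[bonds(b, 0)].push_back(bonds(b, 1));
      ex[bonds(b, 1)].push_back(bonds(b, 0));
    }
    for (int t = 0; t < angles.nrow(); ++t) {
      ang_i.push_back(angles(t, 0));
      ang_j.push_back(angles(t, 1));
      ang_k.push_back(angles(t, 2));
    }
    Kb = ff.Kb; r0 = ff.r0; Ktheta = ff.Ktheta; theta0 = ff.theta0;
  }

  inline bool excluded(int i, int j) const {
    const std::vector<int>& v = ex[i];
    for (size_t k = 0; k < v.size(); ++k) if (v[k] == j) return true;
    return false;
  }

  inline void pair(int i, int j, const double* X, const double* Y,
                   const double* Z, double* fx, double* fy, double* fz,
                   double& energy) const {
    // coordinates are wrapped into [0, box), so differences lie in
    // (-box, box) and one conditional shift realises the minimum image
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    if (dx > hbox) dx -= box; else if (dx < -hbox) dx += box;
    if (dy > hbox) dy -= box; else if (dy < -hbox) dy += box;
    if (dz > hbox) dz -= box; else if (dz < -hbox) dz += box;
    double r2 = dx * dx + dy * dy + dz * dz;
    int a = sp[i], b = sp[j];
    if (r2 >= rc2[a][b] || r2 == 0.0) return;
    if (a == 1 && b == 1 && !ex[i].empty() && excluded(i, j)) return;
    double inv = 1.0 / r2;
    double s2 = sig2[a][b] * inv;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    double e = 4.0 * eps * (s12 - s6);
    double f = 24.0 * eps * (2.0 * s12 - s6) * inv;
    double l = lam[a][b];
    if (r2 <= rmin2[a][b]) {
      energy += e + (1.0 - l) * eps;
    } else {
      energy += l * e;
      f *= l;
    }
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }

  void nonbonded_allpairs(const double* X, const double* Y, const double* Z,
                          double* fx, double* fy, double* fz,
                          double& energy) const {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        pair(i, j, X, Y, Z, fx, fy, fz, energy);
  }

  void nonbonded_cell(const double* X, const double* Y, const double* Z,
                      double* fx, double* fy, double* fz, double& energy) {
    int nc = (int)std::floor(box / max_cut);
    int nc_cap = std::max(3, (int)std::floor(std::cbrt((double)n)));
    if (nc > nc_cap) nc = nc_cap;
    if (nc < 3) { nonbonded_allpairs(X, Y, Z, fx, fy, fz, energy); return; }
    double cell = box / nc;
    int ncells = nc * nc * nc;
    head.assign(ncells, -1);
    nxt.assign(n, -1);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      double px = X[i] - box * std::floor(X[i] * invbox);
      double py = Y[i] - box * std::floor(Y[i] * invbox);
      double pz = Z[i] - box * std::floor(Z[i] * invbox);
      int a = std::min((int)(px / cell), nc - 1);
      int b = std::min((int)(py / cell), nc - 1);
      int c = std::min((int)(pz / cell), nc - 1);
      ci[i] = a; cj[i] = b; ck[i] = c;
      int idx = (a * nc + b) * nc + c;
      nxt[i] = head[idx];
      head[idx] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
          for (int dc = -1; dc <= 1; ++dc) {
            int a = ci[i] + da; a += nc * (a < 0) - nc * (a >= nc);
            int b = cj[i] + db; b += nc * (b < 0) - nc * (b >= nc);
            int c = ck[i] + dc; c += nc * (c < 0) - nc * (c >= nc);
            for (int j = head[(a * nc + b) * nc + c]; j >= 0; j = nxt[j])
              if (j > i) pair(i, j, X, Y, Z, fx, fy, fz, energy);
          }
    }
  }

  void bonded(const double* X, const double* Y, const double* Z,
              double* fx, double* fy, double* fz, double& energy) const {
    for (size_t b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dx = min_image(X[i] - X[j], box);
      double dy = min_image(Y[i] - Y[j], box);
      double dz = min_image(Z[i] - Z[j], box);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - r0;
      energy += Kb * dr * dr;
      double c = -2.0 * Kb * dr / r;  // -dU/dr / r
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    }
    for (size_t t = 0; t < ang_i.size(); ++t) {
      int i = ang_i[t], j = ang_j[t], k = ang_k[t];
      double ax = min_image(X[i] - X[j], box);
      double ay = min_image(Y[i] - Y[j], box);
      double az = min_image(Z[i] - Z[j], box);
      double bx = min_image(X[k] - X[j], box);
      double by = min_image(Y[k] - Y[j], box);
      double bz = min_image(Z[k] - Z[j], box);
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      double ct = (ax * bx + ay * by + az * bz) / (la * lb);
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double theta = std::acos(ct);
      double dth = theta - theta0;
      energy += Ktheta * dth * dth;
      double st = std::sqrt(1.0 - ct * ct);
      // coef = -dU/dcos(theta) = 2 K (theta - theta0) / sin(theta);
      // near theta = pi (theta0 = pi) the ratio has the finite limit -1.
      double coef;
      if (st < 1e-8) {
        coef = (std::fabs(theta0 - M_PI) < 1e-12) ? -2.0 * Ktheta
                                                  : 2.0 * Ktheta * dth / 1e-8;
      } else {
        coef = 2.0 * Ktheta * dth / st;
      }
      double gix = coef * (bx / (la * lb) - ct * ax / (la * la));
      double giy = coef * (by / (la * lb) - ct * ay / (la * la));
      double giz = coef * (bz / (la * lb) - ct * az / (la * la));
      double gkx = coef * (ax / (la * lb) - ct * bx / (lb * lb));
      double gky = coef * (ay / (la * lb) - ct * by / (lb * lb));
      double gkz = coef * (az / (la * lb) - ct * bz / (lb * lb));
      fx[i] += gix; fy[i] += giy; fz[i] += giz;
      fx[k] += gkx; fy[k] += gky; fz[k] += gkz;
      fx[j] -= gix + gkx; fy[j] -= giy + gky; fz[j] -= giz + gkz;
    }
  }

  double forces(const double* X, const double* Y, const double* Z,
                double* fx, double* fy, double* fz, bool use_cell) {
    std::fill(fx, fx + n, 0.0);
    std::fill(fy, fy + n, 0.0);
    std::fill(fz, fz + n, 0.0);
    double energy = 0.0;
    if (use_cell) nonbonded_cell(X, Y, Z, fx, fy, fz, energy);
    else nonbonded_allpairs(X, Y, Z, fx, fy, fz, energy);
    bonded(X, Y, Z, fx, fy, fz, energy);
    return energy;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix positions, IntegerVector species,
                        double box_edge, List ff_list, IntegerMatrix bonds,
                        IntegerMatrix angles, std::string method) {
  FF ff = parse_ff(ff_list);
  Engine eng;
  eng.init(ff, species, box_edge, bonds, angles);
  int n = positions.nrow();
  std::vector<double> X(n), Y(n), Z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    X[i] = positions(i, 0); Y[i] = positions(i, 1); Z[i] = positions(i, 2);
  }
  double energy = eng.forces(X.data(), Y.data(), Z.data(),
                             fx.data(), fy.data(), fz.data(),
                             method == "cell");
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) {
    f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i];
  }
  return List::create(_["forces"] = f, _["energy"] = energy);
}

// BAOAB Langevin integrator. dt and t_damp in internal time units; kT in
// kcal/mol. t_damp = Inf disables the thermostat (plain velocity Verlet).
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix positions, NumericMatrix velocities,
                      IntegerMatrix images, IntegerVector species,
                      NumericVector masses, double box_edge, List ff_list,
                      IntegerMatrix bonds, IntegerMatrix angles, double dt,
                      double t_damp, double kT, int n_steps, int sample_every,
                      bool record_velocities) {
  FF ff = parse_ff(ff_list);
  Engine eng;
  eng.init(ff, species, box_edge, bonds, angles);
  int n = positions.nrow();
  std::vector<double> X(n), Y(n), Z(n), VX(n), VY(n), VZ(n);
  std::vector<int> IX(n), IY(n), IZ(n);
  for (int i = 0; i < n; ++i) {
    X[i] = positions(i, 0); Y[i] = positions(i, 1); Z[i] = positions(i, 2);
    VX[i] = velocities(i, 0); VY[i] = velocities(i, 1); VZ[i] = velocities(i, 2);
    IX[i] = images(i, 0); IY[i] = images(i, 1); IZ[i] = images(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n), sd(n), him(n);
  double half = 0.5 * dt;
  for (int i = 0; i < n; ++i) {
    sd[i] = std::sqrt(kT / masses[i]);
    him[i] = half / masses[i];
  }
  bool thermostat = R_finite(t_damp);
  double c1 = thermostat ? std::exp(-dt / t_damp) : 1.0;
  double c2 = thermostat ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int nf = n_steps / sample_every + 1;
  List frames_x(nf), frames_img(nf), frames_v(nf);
  NumericVector energies(nf), times(nf);

  double energy = eng.forces(X.data(), Y.data(), Z.data(),
                             fx.data(), fy.data(), fz.data(), true);
  double max_disp = 0.5 * box_edge;

  int fr = 0;
  auto record = [&](int step, double e) {
    NumericMatrix px(n, 3), pv(n, 3);
    IntegerMatrix pim(n, 3);
    for (int i = 0; i < n; ++i) {
      px(i, 0) = X[i]; px(i, 1) = Y[i]; px(i, 2) = Z[i];
      pim(i, 0) = IX[i]; pim(i, 1) = IY[i]; pim(i, 2) = IZ[i];
      if (record_velocities) {
        pv(i, 0) = VX[i]; pv(i, 1) = VY[i]; pv(i, 2) = VZ[i];
      }
    }
    frames_x[fr] = px;
    frames_img[fr] = pim;
    if (record_velocities) frames_v[fr] = pv;
    energies[fr] = e;
    times[fr] = dt * step;
    ++fr;
  };
  record(0, energy);

  for (int step = 1; step <= n_steps; ++step) {
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      VX[i] += him[i] * fx[i];
      VY[i] += him[i] * fy[i];
      VZ[i] += him[i] * fz[i];
      X[i] += half * VX[i];
      Y[i] += half * VY[i];
      Z[i] += half * VZ[i];
      double v = std::max(std::fabs(VX[i]),
                          std::max(std::fabs(VY[i]), std::fabs(VZ[i])));
      if (v > vmax) vmax = v;
    }
    if (vmax * half > max_disp)
      stop("bead displacement exceeds half the box in one step (step %d); "
           "reduce the time step or fix overlapping initial coordinates",
           step);
    if (thermostat)
      for (int i = 0; i < n; ++i) {
        VX[i] = c1 * VX[i] + c2 * sd[i] * norm_rand();
        VY[i] = c1 * VY[i] + c2 * sd[i] * norm_rand();
        VZ[i] = c1 * VZ[i] + c2 * sd[i] * norm_rand();
      }
    vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      X[i] += half * VX[i];
      Y[i] += half * VY[i];
      Z[i] += half * VZ[i];
      double v = std::max(std::fabs(VX[i]),
                          std::max(std::fabs(VY[i]), std::fabs(VZ[i])));
      if (v > vmax) vmax = v;
      // wrap into [0, box)
      if (X[i] < 0.0 || X[i] >= box_edge) {
        double w = std::floor(X[i] / box_edge);
        X[i] -= w * box_edge; IX[i] += (int)w;
      }
      if (Y[i] < 0.0 || Y[i] >= box_edge) {
        double w = std::floor(Y[i] / box_edge);
        Y[i] -= w * box_edge; IY[i] += (int)w;
      }
      if (Z[i] < 0.0 || Z[i] >= box_edge) {
        double w = std::floor(Z[i] / box_edge);
        Z[i] -= w * box_edge; IZ[i] += (int)w;
      }
    }
    if (vmax * half > max_disp)
      stop("bead displacement exceeds half the box in one step (step %d); "
           "reduce the time step or fix overlapping initial coordinates",
           step);
    energy = eng.forces(X.data(), Y.data(), Z.data(),
                        fx.data(), fy.data(), fz.data(), true);
    for (int i = 0; i < n; ++i) {
      VX[i] += him[i] * fx[i];
      VY[i] += him[i] * fy[i];
      VZ[i] += him[i] * fz[i];
    }
    if (step % sample_every == 0) record(step, energy);
    if (step % 2000 == 0) checkUserInterrupt();
  }
  NumericMatrix vfinal(n, 3);
  for (int i = 0; i < n; ++i) {
    vfinal(i, 0) = VX[i]; vfinal(i, 1) = VY[i]; vfinal(i, 2) = VZ[i];
  }
  return List::create(_["positions"] = frames_x, _["images"] = frames_img,
                      _["velocities"] = frames_v, _["energies"] = energies,
                      _["times"] = times, _["final_velocities"] = vfinal);
}

// Union-find single-linkage clustering under minimum-image distances.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix positions, double box_edge,
                                 double cutoff) {
  int n = positions.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(positions(i, 0) - positions(j, 0), box_edge);
      if (std::fabs(dx) > cutoff) continue;
      double dy = min_image(positions(i, 1) - positions(j, 1), box_edge);
      if (std::fabs(dy) > cutoff) continue;
      double dz = min_image(positions(i, 2) - positions(j, 2), box_edge);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  IntegerVector lab(n);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] < 0) remap[r] = next++;
    lab[i] = remap[r] + 1;  // 1-based cluster ids
  }
  return lab;
}

// Minimum-image distance from each query bead to the nearest target bead.
// [[Rcpp::export]]
NumericVector cpp_nearest_distance(NumericMatrix query, NumericMatrix target,
                                   double box_edge) {
  int nq = query.nrow(), nt = target.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nt; ++j) {
      double dx = min_image(query(i, 0) - target(j, 0), box_edge);
      double dy = min_image(query(i, 1) - target(j, 1), box_edge);
      double dz = min_image(query(i, 2) - target(j, 2), box_edge);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Pivot Monte Carlo for a single isolated chain (open boundaries, bond
// lengths held at their initial values; angle + nonbonded energies sampled).
// [[Rcpp::export]]
List cpp_pivot_sample(NumericMatrix init, List ff_list, double kT,
                      int n_samples, int thin, int burn) {
  FF ff = parse_ff(ff_list);
  int L = init.nrow();
  std::vector<double> X(L), Y(L), Z(L);
  for (int i = 0; i < L; ++i) { X[i] = init(i, 0); Y[i] = init(i, 1); Z[i] = init(i, 2); }
  double sig = ff.sigma[1];                 // DNA-DNA
  double lam = ff.lambda[1][1];
  double rc = ff.cutoff_factor * sig;
  double rc2 = rc * rc;

  std::vector<double> nx(L), ny(L), nz(L);
  long accepted = 0, attempted = 0;
  List samples(n_samples);
  int collected = 0;

  long total_attempts = (long)burn + (long)n_samples * thin;
  for (long a = 0; a < total_attempts; ++a) {
    int p = 1 + (int)(unif_rand() * (L - 2));  // pivot bead, 1..L-2
    if (p > L - 2) p = L - 2;
    // random rotation axis (Marsaglia) and angle
    double u1, u2, s;
    do { u1 = 2.0 * unif_rand() - 1.0; u2 = 2.0 * unif_rand() - 1.0;
         s = u1 * u1 + u2 * u2; } while (s >= 1.0 || s == 0.0);
    double axx = 2.0 * u1 * std::sqrt(1.0 - s);
    double axy = 2.0 * u2 * std::sqrt(1.0 - s);
    double axz = 1.0 - 2.0 * s;
    double ang = (2.0 * unif_rand() - 1.0) * M_PI;
    double ca = std::cos(ang), sa = std::sin(ang);

    // rotate beads p+1..L-1 about axis through bead p (Rodrigues)
    for (int i = p + 1; i < L; ++i) {
      double vx = X[i] - X[p], vy = Y[i] - Y[p], vz = Z[i] - Z[p];
      double dot = axx * vx + axy * vy + axz * vz;
      double crx = axy * vz - axz * vy;
      double cry = axz * vx - axx * vz;
      double crz = axx * vy - axy * vx;
      nx[i] = X[p] + vx * ca + crx * sa + axx * dot * (1.0 - ca);
      ny[i] = Y[p] + vy * ca + cry * sa + axy * dot * (1.0 - ca);
      nz[i] = Z[p] + vz * ca + crz * sa + axz * dot * (1.0 - ca);
    }
    // angle at pivot bead (p-1, p, p+1): old vs new
    double dE = 0.0;
    {
      double ax0 = X[p - 1] - X[p], ay0 = Y[p - 1] - Y[p], az0 = Z[p - 1] - Z[p];
      double la = std::sqrt(ax0 * ax0 + ay0 * ay0 + az0 * az0);
      double bx0 = X[p + 1] - X[p], by0 = Y[p + 1] - Y[p], bz0 = Z[p + 1] - Z[p];
      double lb = std::sqrt(bx0 * bx0 + by0 * by0 + bz0 * bz0);
      double ct = (ax0 * bx0 + ay0 * by0 + az0 * bz0) / (la * lb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct) - ff.theta0;
      dE -= ff.Ktheta * th * th;
      double bx1 = nx[p + 1] - X[p], by1 = ny[p + 1] - Y[p], bz1 = nz[p + 1] - Z[p];
      double lb1 = std::sqrt(bx1 * bx1 + by1 * by1 + bz1 * bz1);
      double ct1 = (ax0 * bx1 + ay0 * by1 + az0 * bz1) / (la * lb1);
      ct1 = std::max(-1.0, std::min(1.0, ct1));
      double th1 = std::acos(ct1) - ff.theta0;
      dE += ff.Ktheta * th1 * th1;
    }
    // nonbonded between fixed [0..p] and moved [p+1..L-1]; skip bond (p,p+1)
    for (int i = 0; i <= p && dE < 500.0 * kT; ++i) {
      int jstart = (i == p) ? p + 2 : p + 1;
      for (int j = jstart; j < L; ++j) {
        double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) dE -= ah_energy(r2, sig, lam, ff.eps);
        dx = X[i] - nx[j]; dy = Y[i] - ny[j]; dz = Z[i] - nz[j];
        r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) dE += ah_energy(r2, sig, lam, ff.eps);
      }
    }
    ++attempted;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
      for (int i = p + 1; i < L; ++i) { X[i] = nx[i]; Y[i] = ny[i]; Z[i] = nz[i]; }
      ++accepted;
    }
    if (a >= burn && (a - burn + 1) % thin == 0 && collected < n_samples) {
      NumericMatrix m(L, 3);
      for (int i = 0; i < L; ++i) { m(i, 0) = X[i]; m(i, 1) = Y[i]; m(i, 2) = Z[i]; }
      samples[collected++] = m;
    }
    if (a % 5000 == 0) checkUserInterrupt();
  }
  return List::create(_["samples"] = samples,
                      _["acceptance"] = (double)accepted / (double)attempted);
}

// Random-sequential placement of a protein/DNA mixture inside a central
// sphere, with rejection-based overlap relief.  Proteins are placed first,
// then each DNA chain is grown as a mildly perturbed random walk with bond
// length r0.  Overlap thresholds are 0.8 * sigma_ij per species pair.
// [[Rcpp::export]]
List cpp_place_mixture(int n_protein, int n_chains, int chain_len,
                       double box_edge, double radius, List ff_list,
                       int max_retries) {
  FF ff = parse_ff(ff_list);
  int n_dna = n_chains * chain_len;
  int n = n_protein + n_dna;
  NumericMatrix pos(n, 3);
  IntegerVector sp(n);
  double cx = 0.5 * box_edge;
  double thr[2][2];
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) thr[a][b] = 0.8 * ff.sig_ij(a, b);

  int placed = 0;
  std::function<bool(double, double, double, int)> clash =
      [&](double x, double y, double z, int s) {
    for (int j = 0; j < placed; ++j) {
      double t = thr[s][sp[j]];
      double dx = x - pos(j, 0);
      if (std::fabs(dx) > t) continue;
      double dy = y - pos(j, 1);
      if (std::fabs(dy) > t) continue;
      double dz = z - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz < t * t) return true;
    }
    return false;
  };
  std::function<bool(double*, double*, double*)> draw_in_sphere =
      [&](double* x, double* y, double* z) {
    for (int k = 0; k < 100; ++k) {
      double a = (2.0 * unif_rand() - 1.0) * radius;
      double b = (2.0 * unif_rand() - 1.0) * radius;
      double c = (2.0 * unif_rand() - 1.0) * radius;
      if (a * a + b * b + c * c <= radius * radius) {
        *x = cx + a; *y = cx + b; *z = cx + c;
        return true;
      }
    }
    return false;
  };

  for (int i = 0; i < n_protein; ++i) {
    bool ok = false;
    for (int r = 0; r < max_retries && !ok; ++r) {
      double x, y, z;
      if (!draw_in_sphere(&x, &y, &z)) continue;
      if (!clash(x, y, z, 0)) {
        pos(placed, 0) = x; pos(placed, 1) = y; pos(placed, 2) = z;
        sp[placed] = 0;
        ok = true;
      }
    }
    if (!ok)
      stop("infeasible packing: could not place protein bead %d within the "
           "placement sphere after %d retries", i + 1, max_retries);
    ++placed;
  }

  for (int c = 0; c < n_chains; ++c) {
    bool chain_ok = false;
    for (int attempt = 0; attempt < 20 && !chain_ok; ++attempt) {
      int start = placed;
      double x, y, z;
      bool ok = false;
      for (int r = 0; r < max_retries && !ok; ++r) {
        if (!draw_in_sphere(&x, &y, &z)) continue;
        if (!clash(x, y, z, 1)) ok = true;
      }
      if (!ok) continue;
      pos(placed, 0) = x; pos(placed, 1) = y; pos(placed, 2) = z;
      sp[placed] = 1;
      ++placed;
      // grow the walk with a persistent, mildly perturbed direction
      double dx = norm_rand(), dy = norm_rand(), dz = norm_rand();
      double nn = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= nn; dy /= nn; dz /= nn;
      bool grown = true;
      for (int b = 1; b < chain_len; ++b) {
        bool bok = false;
        double px = pos(placed - 1, 0), py = pos(placed - 1, 1),
               pz = pos(placed - 1, 2);
        for (int r = 0; r < max_retries && !bok; ++r) {
          double ex = dx + 0.4 * norm_rand();
          double ey = dy + 0.4 * norm_rand();
          double ez = dz + 0.4 * norm_rand();
          double en = std::sqrt(ex * ex + ey * ey + ez * ez);
          ex /= en; ey /= en; ez /= en;
          double qx = px + ff.r0 * ex, qy = py + ff.r0 * ey,
                 qz = pz + ff.r0 * ez;
          double rx = qx - cx, ry = qy - cx, rz = qz - cx;
          if (rx * rx + ry * ry + rz * rz > radius * radius) {
            dx = norm_rand(); dy = norm_rand(); dz = norm_rand();
            double m = std::sqrt(dx * dx + dy * dy + dz * dz);
            dx /= m; dy /= m; dz /= m;
            continue;
          }
          if (clash(qx, qy, qz, 1)) continue;
          pos(placed, 0) = qx; pos(placed, 1) = qy; pos(placed, 2) = qz;
          sp[placed] = 1;
          ++placed;
          dx = ex; dy = ey; dz = ez;
          bok = true;
        }
        if (!bok) { grown = false; break; }
      }
      if (grown) {
        chain_ok = true;
      } else {
        placed = start;  // discard partial chain and retry
      }
    }
    if (!chain_ok)
      stop("infeasible packing: could not grow DNA chain %d within the "
           "placement sphere", c + 1);
  }
  return List::create(_["positions"] = pos, _["species"] = sp);
}

// Union-find clustering with per-species-pair cutoffs factor * sigma_ij.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels_perpair(NumericMatrix positions,
                                         IntegerVector species,
                                         double box_edge,
                                         NumericVector cutoffs) {
  // cutoffs: length 4, [PP, PD, DP, DD] linking distances
  int n = positions.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ct = cutoffs[2 * species[i] + species[j]];
      double dx = min_image(positions(i, 0) - positions(j, 0), box_edge);
      if (std::fabs(dx) > ct) continue;
      double dy = min_image(positions(i, 1) - positions(j, 1), box_edge);
      if (std::fabs(dy) > ct) continue;
      double dz = min_image(positions(i, 2) - positions(j, 2), box_edge);
      if (dx * dx + dy * dy + dz * dz <= ct * ct) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  IntegerVector lab(n);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] < 0) remap[r] = next++;
    lab[i] = remap[r] + 1;
  }
  return lab;
}
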