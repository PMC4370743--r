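// Grid kernels for the tightly-bound-ion electrostatics engine:
// signed-distance maps, charge spreading, Dirichlet boundary fill,
// damped-Newton / SOR nonlinear Poisson-Boltzmann relaxation,
// diffusive-ion free-energy functionals, and the Coulomb-field
// Generalized Born volume integral.
//
// All potentials are in units of kBT/e, lengths in Angstrom,
// concentrations in ions per cubic Angstrom.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double BIG_DIST = 1e30;
// cap on |z*u| inside Boltzmann factors; keeps exp() finite in the Stern
// layer where the mean-field factor is unphysical anyway
static const double EXP_CAP = 40.0;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Signed distance from each grid node to the union-of-spheres molecular
// surface: d = min_a(|r - r_a| - R_a). Exact only within `reach` of some
// atom; farther nodes keep BIG_DIST (they are plain solvent).
// [[Rcpp::export]]
NumericVector cpp_surface_distance(NumericMatrix atoms, NumericVector origin,
                                   double h, IntegerVector dims, double reach) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n, BIG_DIST);
  int na = atoms.nrow();
  for (int a = 0; a < na; ++a) {
    double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2), ar = atoms(a, 3);
    double rr = ar + reach;
    int i0 = std::max(0, (int)std::ceil((ax - rr - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((ax + rr - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((ay - rr - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((ay + rr - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((az - rr - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((az + rr - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - ay;
        double dyz = dy * dy + dz * dz;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - ax;
          double dist = std::sqrt(dx * dx + dyz) - ar;
          R_xlen_t id = idx3(i, j, k, nx, ny);
          if (dist < d[id]) d[id] = dist;
        }
      }
    }
  }
  return d;
}

// Trilinear spreading of point charges (columns x,y,z,q) onto grid nodes.
// [[Rcpp::export]]
NumericVector cpp_spread_charges(NumericMatrix chg, NumericVector origin,
                                 double h, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector rho(n, 0.0);
  for (int c = 0; c < chg.nrow(); ++c) {
    double fx = (chg(c, 0) - origin[0]) / h;
    double fy = (chg(c, 1) - origin[1]) / h;
    double fz = (chg(c, 2) - origin[2]) / h;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1)
      stop("charge outside grid");
    double wx = fx - i, wy = fy - j, wz = fz - k, q = chg(c, 3);
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
          rho[idx3(i + di, j + dj, k + dk, nx, ny)] += q * w;
        }
  }
  return rho;
}

// Fill the six faces of a grid with the screened-Coulomb superposition
// u = (C/eps_w) * sum_q q * exp(-kappa d)/d  (kappa = 0 gives plain Coulomb).
// Interior nodes are left at their incoming values.
// [[Rcpp::export]]
NumericVector cpp_face_potential(NumericVector u0, NumericMatrix chg,
                                 NumericVector origin, double h, IntegerVector dims,
                                 double kappa, double epsw, double coulC) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector u = clone(u0);
  int nq = chg.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1)
          continue;
        double x = origin[0] + i * h, y = origin[1] + j * h, z = origin[2] + k * h;
        double v = 0.0;
        for (int c = 0; c < nq; ++c) {
          double dx = x - chg(c, 0), dy = y - chg(c, 1), dz = z - chg(c, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 1e-6) d = 1e-6;
          v += chg(c, 3) * std::exp(-kappa * d) / d;
        }
        u[idx3(i, j, k, nx, ny)] = coulC * v / epsw;
      }
  return u;
}

static inline double hmean(double a, double b) { return 2.0 * a * b / (a + b); }

// Nonlinear PB relaxation. eps: node dielectric; rho: fixed charge (e) per
// node; acc: per-species ion accessibility (0/1) flattened species-major;
// z, cbulk: species valences and bulk number densities (1/A^3).
// u0 carries the Dirichlet faces. Solves
//   div(eps grad u) + 4 pi C [rho/h^3 + sum_a z_a c_a acc_a exp(-z_a u)] = 0
// by outer damped-Newton linearization of the mobile term and inner
// red-black SOR sweeps. Returns u, iteration counts, and the max step.
// [[Rcpp::export]]
List cpp_solve_pb(NumericVector eps, NumericVector rho, NumericMatrix acc,
                  NumericVector z, NumericVector cbulk, NumericVector u0,
                  IntegerVector dims, double h, double fourpiC, double tol,
                  int max_outer, int max_inner, double omega) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int ns = z.size();
  NumericVector u = clone(u0);
  std::vector<double> rhs0(n), dex(n); // Newton-frozen source and extra diagonal
  std::vector<double> b0(n);
  for (R_xlen_t t = 0; t < n; ++t) b0[t] = fourpiC * rho[t] / h;
  double h2 = h * h;
  double outer_step = 0.0;
  int outer;
  bool converged = false;
  std::vector<double> uprev(n);
  for (outer = 1; outer <= max_outer; ++outer) {
    for (R_xlen_t t = 0; t < n; ++t) uprev[t] = u[t];
    // freeze Newton linearization of the Boltzmann source at current u
    for (R_xlen_t t = 0; t < n; ++t) {
      double S0 = 0.0, Sp = 0.0;
      for (int a = 0; a < ns; ++a) {
        if (cbulk[a] <= 0.0 || acc(t, a) == 0.0) continue;
        double x = -z[a] * u[t];
        if (x > EXP_CAP) x = EXP_CAP;
        if (x < -EXP_CAP) x = -EXP_CAP;
        double e = std::exp(x);
        S0 += z[a] * cbulk[a] * e;
        Sp += z[a] * z[a] * cbulk[a] * e;
      }
      rhs0[t] = b0[t] + fourpiC * h2 * (S0 + Sp * u[t]);
      dex[t] = fourpiC * h2 * Sp;
    }
    // inner red-black SOR on the linearized problem
    double inner_tol = std::max(tol * 0.2, 1e-9);
    double md = 0.0;
    for (int it = 0; it < max_inner; ++it) {
      md = 0.0;
      for (int rb = 0; rb < 2; ++rb) {
        for (int k = 1; k < nz - 1; ++k)
          for (int j = 1; j < ny - 1; ++j) {
            int istart = 1 + ((j + k + 1 + rb) % 2);
            for (int i = istart; i < nx - 1; i += 2) {
              R_xlen_t t = idx3(i, j, k, nx, ny);
              double ec = eps[t];
              double exm = hmean(ec, eps[t - 1]), exp_ = hmean(ec, eps[t + 1]);
              double eym = hmean(ec, eps[t - nx]), eyp = hmean(ec, eps[t + nx]);
              R_xlen_t sz = (R_xlen_t)nx * ny;
              double ezm = hmean(ec, eps[t - sz]), ezp = hmean(ec, eps[t + sz]);
              double se = exm + exp_ + eym + eyp + ezm + ezp;
              double num = exm * u[t - 1] + exp_ * u[t + 1] + eym * u[t - nx] +
                           eyp * u[t + nx] + ezm * u[t - sz] + ezp * u[t + sz] +
                           rhs0[t];
              double unew = (1.0 - omega) * u[t] + omega * num / (se + dex[t]);
              double dd = std::fabs(unew - u[t]);
              if (dd > md) md = dd;
              u[t] = unew;
            }
          }
      }
      if (md < inner_tol) break;
    }
    // outer convergence: max change of u over this whole Newton iterate
    outer_step = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) {
      double dd = std::fabs(u[t] - uprev[t]);
      if (dd > outer_step) outer_step = dd;
    }
    if (outer > 1 && outer_step < tol) { converged = true; break; }
  }
  return List::create(_["u"] = u, _["outer"] = outer,
                      _["converged"] = converged, _["max_step"] = outer_step);
}

// Diffusive-ion functionals on one grid.
//  dU_d   = 1/2 sum_nodes sum_a c_a z_a (u + uprime) h^3          [kBT]
//  S_int  = sum_nodes sum_a [c ln(c/c0) - c + c0] h^3             [kB]
//           (inaccessible nodes contribute c0 per species: c = 0)
//  excess_a = sum_nodes (c_a - c0_a) h^3                          [ions]
// `include` masks nodes belonging to this grid's share of the volume
// (used to splice fine and coarse grids without double counting).
// [[Rcpp::export]]
List cpp_pb_functionals(NumericVector u, NumericVector uprime, NumericMatrix acc,
                        LogicalVector include, NumericVector z, NumericVector cbulk,
                        double h) {
  R_xlen_t n = u.size();
  int ns = z.size();
  double h3 = h * h * h;
  double du = 0.0, sint = 0.0;
  NumericVector excess(ns, 0.0);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!include[t]) continue;
    for (int a = 0; a < ns; ++a) {
      double c0 = cbulk[a];
      if (c0 <= 0.0) continue;
      if (acc(t, a) == 0.0) {
        sint += c0 * h3;
        excess[a] -= c0 * h3;
        continue;
      }
      double x = -z[a] * u[t];
      if (x > EXP_CAP) x = EXP_CAP;
      if (x < -EXP_CAP) x = -EXP_CAP;
      double c = c0 * std::exp(x);
      du += 0.5 * c * z[a] * (u[t] + uprime[t]) * h3;
      sint += (c * x - c + c0) * h3; // c*ln(c/c0) = c*x
      excess[a] += (c - c0) * h3;
    }
  }
  return List::create(_["du_d"] = du, _["s_integral"] = sint,
                      _["excess"] = excess);
}

// Coulomb-field Generalized Born integral. For each point with intrinsic
// radius a:  1/B = 1/a - (1/4pi) * I,  I = integral over the low-dielectric
// region outside the point's own sphere of dV/d^4. solute_nodes columns are
// x,y,z,w with w the node's solute volume fraction. Voxels closer than
// a + 2h are subsampled 3x3x3 to tame the d^-4 singularity at the sphere.
// [[Rcpp::export]]
NumericVector cpp_born_integral(NumericMatrix pts, NumericVector a,
                                NumericMatrix solute_nodes, double h) {
  int np = pts.nrow(), nn = solute_nodes.nrow();
  NumericVector B(np);
  double h3 = h * h * h;
  double third = h / 3.0;
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2), ap = a[p];
    double near2 = (ap + 2.0 * h) * (ap + 2.0 * h);
    double I = 0.0;
    for (int j = 0; j < nn; ++j) {
      double dx = solute_nodes(j, 0) - px, dy = solute_nodes(j, 1) - py,
             dz = solute_nodes(j, 2) - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      double w = solute_nodes(j, 3);
      if (d2 >= near2) {
        I += w * h3 / (d2 * d2);
      } else {
        double sub = w * h3 / 27.0;
        for (int sk = -1; sk <= 1; ++sk)
          for (int sj = -1; sj <= 1; ++sj)
            for (int si = -1; si <= 1; ++si) {
              double sx = dx + si * third, sy = dy + sj * third, sz = dz + sk * third;
              double s2 = sx * sx + sy * sy + sz * sz;
              if (s2 >= ap * ap) I += sub / (s2 * s2);
            }
      }
    }
    double inv = 1.0 / ap - I / (4.0 * M_PI);
    B[p] = (inv > 1e-6) ? 1.0 / inv : 1e6;
  }
  return B;
}

// Exact min_a(|r - r_a| - R_a) for arbitrary points (no reach cap).
// [[Rcpp::export]]
NumericVector cpp_point_surface_distance(NumericMatrix pts, NumericMatrix atoms) {
  int np = pts.nrow(), na = atoms.nrow();
  NumericVector d(np, BIG_DIST);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double best = BIG_DIST;
    for (int a = 0; a < na; ++a) {
      double dx = px - atoms(a, 0), dy = py - atoms(a, 1), dz = pz - atoms(a, 2);
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz) - atoms(a, 3);
      if (dist < best) best = dist;
    }
    d[p] = best;
  }
  return d;
}
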