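#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D index helper, column-major like R arrays
static inline int at(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Ghost index for the zero-flux boundary: the ghost node mirrors the
// boundary node itself (flux form), which makes the discrete Laplacian
// conservative — the lattice sum is invariant without decay or sources.
static inline int mirror(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// One FTCS update of a scalar field on a uniform cubic lattice.
// u' = (1 - lam*dt) u + D*dt/h^2 * (6-point Laplacian)
//      + dt*(1-u)*Ap - dt*u*Am
// bc: 0 = Neumann zero-flux (ghost node = boundary node, flux form),
//     1 = Dirichlet (boundary nodes held at bc_value).
// [[Rcpp::export]]
NumericVector cpp_ftcs_step(NumericVector u, IntegerVector dim, double h,
                            double D, double lam, double dt,
                            NumericVector Ap, NumericVector Am,
                            int bc, double bc_value) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ddt = D * dt / (h * h);
  NumericVector out(u.size());
  const bool has_ap = Ap.size() == u.size();
  const bool has_am = Am.size() == u.size();

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int id = at(i, j, k, nx, ny);
        if (bc == 1 && (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                        k == 0 || k == nz - 1)) {
          out[id] = bc_value;
          continue;
        }
        const double uc = u[id];
        double lap;
        if (bc == 1) {
          // interior of a Dirichlet grid never touches ghost nodes
          lap = u[at(i + 1, j, k, nx, ny)] + u[at(i - 1, j, k, nx, ny)] +
                u[at(i, j + 1, k, nx, ny)] + u[at(i, j - 1, k, nx, ny)] +
                u[at(i, j, k + 1, nx, ny)] + u[at(i, j, k - 1, nx, ny)] -
                6.0 * uc;
        } else {
          lap = u[at(mirror(i + 1, nx), j, k, nx, ny)] +
                u[at(mirror(i - 1, nx), j, k, nx, ny)] +
                u[at(i, mirror(j + 1, ny), k, nx, ny)] +
                u[at(i, mirror(j - 1, ny), k, nx, ny)] +
                u[at(i, j, mirror(k + 1, nz), nx, ny)] +
                u[at(i, j, mirror(k - 1, nz), nx, ny)] - 6.0 * uc;
        }
        double v = (1.0 - lam * dt) * uc + ddt * lap;
        if (has_ap) v += dt * (1.0 - uc) * Ap[id];
        if (has_am) v -= dt * uc * Am[id];
        out[id] = v;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Piecewise-polynomial two-particle force magnitude (positive = repulsive,
// acting along the center line from j to i). Zero at and beyond d = RA,
// continuous in d; quadratic repulsion below the physical-radius sum Rp,
// quadratic adhesive well up to the action-radius sum RA.
static inline double force_mag(double d, double Rp, double RA,
                               double c_rep, double c_adh) {
  if (d >= RA) return 0.0;
  double f = 0.0;
  if (d < Rp) {
    const double s = (Rp - d) / Rp;
    f += c_rep * s * s;
  }
  const double a = (RA - d) / RA;
  f -= c_adh * a * a;
  return f;
}

// [[Rcpp::export]]
double cpp_force_magnitude(double d, double Rp, double RA, double c_rep,
                           double c_adh) {
  return force_mag(d, Rp, RA, c_rep, c_adh);
}

// Pairwise force sum over a uniform bucket grid with spacing
// 2 * max(action radius). Exact: every pair within range is visited once;
// forces are accumulated antisymmetrically so Newton's third law holds to
// the bit. Coincident centers (d < 1e-9) repel along the caller-supplied
// tie-break direction for the lower-index cell; the caller learns about
// such pairs through the `coincident` entry and may redraw directions.
// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, NumericVector rp, NumericVector ra,
                      double c_rep, double c_adh, NumericMatrix tie_dirs) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<int> coincident;
  if (n < 2) return List::create(_["forces"] = F,
                                 _["coincident"] = IntegerVector(0));

  double ra_max = 0.0;
  for (int i = 0; i < n; ++i) ra_max = std::max(ra_max, ra[i]);
  const double hg = 2.0 * ra_max;

  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = pos(0, c); hi[c] = pos(0, c);
    for (int i = 1; i < n; ++i) {
      lo[c] = std::min(lo[c], pos(i, c));
      hi[c] = std::max(hi[c], pos(i, c));
    }
  }
  int nb[3];
  for (int c = 0; c < 3; ++c)
    nb[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / hg) + 1);
  const int nbuck = nb[0] * nb[1] * nb[2];

  std::vector<std::vector<int> > bucket(nbuck);
  std::vector<int> bix(n), biy(n), biz(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(nb[0] - 1, (int)std::floor((pos(i, 0) - lo[0]) / hg));
    int iy = std::min(nb[1] - 1, (int)std::floor((pos(i, 1) - lo[1]) / hg));
    int iz = std::min(nb[2] - 1, (int)std::floor((pos(i, 2) - lo[2]) / hg));
    bix[i] = ix; biy[i] = iy; biz[i] = iz;
    bucket[ix + nb[0] * (iy + nb[1] * iz)].push_back(i);
  }

  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      const int kz = biz[i] + dz;
      if (kz < 0 || kz >= nb[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int ky = biy[i] + dy;
        if (ky < 0 || ky >= nb[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int kx = bix[i] + dx;
          if (kx < 0 || kx >= nb[0]) continue;
          const std::vector<int>& cand = bucket[kx + nb[0] * (ky + nb[1] * kz)];
          for (size_t q = 0; q < cand.size(); ++q) {
            const int j = cand[q];
            if (j <= i) continue;  // each pair once
            const double ddx = pos(i, 0) - pos(j, 0);
            const double ddy = pos(i, 1) - pos(j, 1);
            const double ddz = pos(i, 2) - pos(j, 2);
            const double RA = ra[i] + ra[j];
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 >= RA * RA) continue;
            const double d = std::sqrt(d2);
            double ux, uy, uz, f;
            if (d < eps) {
              coincident.push_back(i + 1);  // 1-based for R
              double tx = tie_dirs(i, 0), ty = tie_dirs(i, 1),
                     tz = tie_dirs(i, 2);
              double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
              if (tn < eps) { tx = 1.0; ty = 0.0; tz = 0.0; tn = 1.0; }
              ux = tx / tn; uy = ty / tn; uz = tz / tn;
              f = c_rep;  // pure repulsion at zero separation
            } else {
              ux = ddx / d; uy = ddy / d; uz = ddz / d;
              f = force_mag(d, rp[i] + rp[j], RA, c_rep, c_adh);
            }
            F(i, 0) += f * ux; F(i, 1) += f * uy; F(i, 2) += f * uz;
            F(j, 0) -= f * ux; F(j, 1) -= f * uy; F(j, 2) -= f * uz;
          }
        }
      }
    }
  }
  return List::create(_["forces"] = F,
                      _["coincident"] = wrap(coincident));
}

// Accumulate weights onto flattened lattice nodes (1-based 3-D indices).
// [[Rcpp::export]]
NumericVector cpp_deposit(IntegerMatrix idx, NumericVector w, int n) {
  NumericVector A(n * n * n);
  const int m = idx.nrow();
  for (int r = 0; r < m; ++r) {
    A[(idx(r, 0) - 1) + n * ((idx(r, 1) - 1) + n * (idx(r, 2) - 1))] += w[r];
  }
  A.attr("dim") = IntegerVector::create(n, n, n);
  return A;
}
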