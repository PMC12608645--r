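#include "diffusion.h"
#include <Rcpp.h>
#include <cmath>
#include <algorithm>

// index helper: column-major like R matrices, c[i + nx*j], i = x, j = y
static inline int idx(int i, int j, int nx) { return i + nx * j; }

// General Thomas solve; a = sub-diagonal, b = diagonal, cc = super-diagonal.
// d: rhs in, solution out.
static void thomas(int n, const double* a, const double* b, const double* cc,
                   double* d, double* cp) {
  cp[0] = cc[0] / b[0];
  d[0] = d[0] / b[0];
  for (int i = 1; i < n; ++i) {
    double m = b[i] - a[i] * cp[i - 1];
    cp[i] = cc[i] / m;
    d[i] = (d[i] - a[i] * d[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
}

// bc_kind: 0 = Dirichlet all around, 1 = zero-flux all around,
// 2 = Dirichlet on the x ends, zero-flux on the y sides (1D strip mode).
static void clamp_bc(std::vector<double>& c, int nx, int ny, int bc_kind,
                     double v) {
  if (bc_kind == 1) return;
  for (int j = 0; j < ny; ++j) {
    c[idx(0, j, nx)] = v;
    c[idx(nx - 1, j, nx)] = v;
  }
  if (bc_kind == 0) {
    for (int i = 0; i < nx; ++i) {
      c[idx(i, 0, nx)] = v;
      c[idx(i, ny - 1, nx)] = v;
    }
  }
}

// Fill tridiagonal coefficients for one implicit sweep of length n.
static void fill_coefs(int n, double alpha, bool dirichlet, double* a,
                       double* b, double* cc) {
  for (int i = 0; i < n; ++i) {
    a[i] = -alpha;
    b[i] = 1.0 + 2.0 * alpha;
    cc[i] = -alpha;
  }
  if (dirichlet) {
    a[0] = 0.0;  b[0] = 1.0;  cc[0] = 0.0;
    a[n - 1] = 0.0;  b[n - 1] = 1.0;  cc[n - 1] = 0.0;
  } else {
    b[0] = 1.0 + alpha;  a[0] = 0.0;
    b[n - 1] = 1.0 + alpha;  cc[n - 1] = 0.0;
  }
}

double adi_step(std::vector<double>& c, int nx, int ny, double D, double dt_min,
                double h_um, int bc_kind, double bc_value,
                const double* source) {
  const double alpha = D * dt_min / (2.0 * h_um * h_um);
  const bool dir_x = (bc_kind == 0 || bc_kind == 2);
  const bool dir_y = (bc_kind == 0);
  double clipped = 0.0;

  // volumetric source first (explicit), floor at zero and log clipped mass
  if (source) {
    for (int k = 0; k < nx * ny; ++k) {
      c[k] += dt_min * source[k];
      if (c[k] < 0.0) {
        clipped += -c[k];
        c[k] = 0.0;
      }
    }
    clamp_bc(c, nx, ny, bc_kind, bc_value);
  }

  const int nmax = std::max(nx, ny);
  std::vector<double> cs(nx * ny), line(nmax), cp(nmax);
  std::vector<double> ax(nmax), bx(nmax), cx(nmax), ay(nmax), by(nmax), cy(nmax);
  fill_coefs(nx, alpha, dir_x, ax.data(), bx.data(), cx.data());
  fill_coefs(ny, alpha, dir_y, ay.data(), by.data(), cy.data());

  // ---- half step 1: implicit in x, explicit in y ----
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double cij = c[idx(i, j, nx)];
      double up = (j + 1 < ny) ? c[idx(i, j + 1, nx)] : cij;
      double dn = (j - 1 >= 0) ? c[idx(i, j - 1, nx)] : cij;
      double lap_y;
      if (j == 0) lap_y = dir_y ? (up - 2.0 * cij + bc_value) : (up - cij);
      else if (j == ny - 1) lap_y = dir_y ? (bc_value - 2.0 * cij + dn) : (dn - cij);
      else lap_y = up - 2.0 * cij + dn;
      line[i] = cij + alpha * lap_y;
    }
    if (dir_x) { line[0] = bc_value; line[nx - 1] = bc_value; }
    thomas(nx, ax.data(), bx.data(), cx.data(), line.data(), cp.data());
    for (int i = 0; i < nx; ++i) cs[idx(i, j, nx)] = line[i];
  }
  clamp_bc(cs, nx, ny, bc_kind, bc_value);

  // ---- half step 2: implicit in y, explicit in x ----
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      double cij = cs[idx(i, j, nx)];
      double rt = (i + 1 < nx) ? cs[idx(i + 1, j, nx)] : cij;
      double lf = (i - 1 >= 0) ? cs[idx(i - 1, j, nx)] : cij;
      double lap_x;
      if (i == 0) lap_x = dir_x ? (rt - 2.0 * cij + bc_value) : (rt - cij);
      else if (i == nx - 1) lap_x = dir_x ? (bc_value - 2.0 * cij + lf) : (lf - cij);
      else lap_x = rt - 2.0 * cij + lf;
      line[j] = cij + alpha * lap_x;
    }
    if (dir_y) { line[0] = bc_value; line[ny - 1] = bc_value; }
    thomas(ny, ay.data(), by.data(), cy.data(), line.data(), cp.data());
    for (int j = 0; j < ny; ++j) c[idx(i, j, nx)] = line[j];
  }
  clamp_bc(c, nx, ny, bc_kind, bc_value);

  for (int k = 0; k < nx * ny; ++k) {
    if (!std::isfinite(c[k]))
      Rcpp::stop("diffusion solver produced a non-finite value");
    if (c[k] < 0.0) { clipped += -c[k]; c[k] = 0.0; }
  }
  return clipped;
}
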