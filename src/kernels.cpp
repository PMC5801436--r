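#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// mu0 / (4 pi) with mu0 = 4 pi x 1e-7 T m / A
static const double MU0_4PI = 1e-7;

// ---------------------------------------------------------------------------
// Gauss-Legendre rules on [0, 1]
// ---------------------------------------------------------------------------

static void gauss01(int n, std::vector<double>& x, std::vector<double>& w) {
  x.clear(); w.clear();
  switch (n) {
  case 1:
    x = {0.5}; w = {1.0};
    break;
  case 2: {
    double a = 0.5 / std::sqrt(3.0);
    x = {0.5 - a, 0.5 + a}; w = {0.5, 0.5};
    break;
  }
  case 3: {
    double a = 0.5 * std::sqrt(0.6);
    x = {0.5 - a, 0.5, 0.5 + a};
    w = {5.0 / 18.0, 8.0 / 18.0, 5.0 / 18.0};
    break;
  }
  case 4: {
    double a1 = 0.3399810435848563, a2 = 0.8611363115940526;
    double w1 = 0.6521451548625461, w2 = 0.3478548451374538;
    x = {0.5 * (1 - a2), 0.5 * (1 - a1), 0.5 * (1 + a1), 0.5 * (1 + a2)};
    w = {0.5 * w2, 0.5 * w1, 0.5 * w1, 0.5 * w2};
    break;
  }
  default: {
    double a1 = 0.5384693101056831, a2 = 0.9061798459386640;
    double w0 = 0.5688888888888889, w1 = 0.4786286704993665,
      w2 = 0.2369268850561891;
    x = {0.5 * (1 - a2), 0.5 * (1 - a1), 0.5, 0.5 * (1 + a1), 0.5 * (1 + a2)};
    w = {0.5 * w2, 0.5 * w1, 0.5 * w0, 0.5 * w1, 0.5 * w2};
  }
  }
}

// ---------------------------------------------------------------------------
// Trilinear basis on the unit cube; corner j has bits (dx, dy, dz) with
// j = dx + 2 dy + 4 dz, matching the element connectivity ordering.
// ---------------------------------------------------------------------------

static inline void basis_val(const double xi[3], double N[8]) {
  double x = xi[0], y = xi[1], z = xi[2];
  double mx = 1 - x, my = 1 - y, mz = 1 - z;
  N[0] = mx * my * mz; N[1] = x * my * mz;
  N[2] = mx * y * mz;  N[3] = x * y * mz;
  N[4] = mx * my * z;  N[5] = x * my * z;
  N[6] = mx * y * z;   N[7] = x * y * z;
}

// gradient with respect to local coordinates (physical gradient = G / h)
static inline void basis_grad(const double xi[3], double G[8][3]) {
  double x = xi[0], y = xi[1], z = xi[2];
  double mx = 1 - x, my = 1 - y, mz = 1 - z;
  const double sx[8] = {-1, 1, -1, 1, -1, 1, -1, 1};
  double fy[8] = {my, my, y, y, my, my, y, y};
  double fz[8] = {mz, mz, mz, mz, z, z, z, z};
  double fx[8] = {mx, x, mx, x, mx, x, mx, x};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int j = 0; j < 8; ++j) {
    G[j][0] = sx[j] * fy[j] * fz[j];
    G[j][1] = sy[j] * fx[j] * fz[j];
    G[j][2] = sz[j] * fx[j] * fy[j];
  }
}

// gradient of the singularity potential u_inf of a point dipole (M at r0)
// in an unbounded homogeneous conductor of conductivity sinf:
//   u_inf(r) = M . a / (4 pi sinf |a|^3),  a = r - r0
//   grad u_inf = ( M / |a|^3 - 3 (M . a) a / |a|^5 ) / (4 pi sinf)
static inline void grad_uinf(const double* x, const double* r0,
                             const double* M, double sinf, double* g) {
  double a0 = x[0] - r0[0], a1 = x[1] - r0[1], a2 = x[2] - r0[2];
  double n2 = a0 * a0 + a1 * a1 + a2 * a2;
  double n = std::sqrt(n2);
  double n3 = n2 * n, n5 = n3 * n2;
  double ma = M[0] * a0 + M[1] * a1 + M[2] * a2;
  double c = 1.0 / (4.0 * M_PI * sinf);
  g[0] = c * (M[0] / n3 - 3.0 * ma * a0 / n5);
  g[1] = c * (M[1] / n3 - 3.0 * ma * a1 / n5);
  g[2] = c * (M[2] / n3 - 3.0 * ma * a2 / n5);
}

// quad points of a face of the unit cube: axis `a` fixed at coordinate c
struct FaceQuad {
  std::vector<double> xi;   // 3 * nq local coords
  std::vector<double> w;    // nq weights (2D product)
};

static FaceQuad face_quad(int a, double c, int q) {
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  int t1 = (a == 0) ? 1 : 0;
  int t2 = (a == 2) ? 1 : 2;
  FaceQuad fq;
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) {
      double xi[3];
      xi[a] = c; xi[t1] = gx[i]; xi[t2] = gx[j];
      fq.xi.insert(fq.xi.end(), xi, xi + 3);
      fq.w.push_back(gw[i] * gw[j]);
    }
  return fq;
}

// ---------------------------------------------------------------------------
// Reference matrices
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_ref_stiffness(int q) {
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  NumericMatrix K(8, 8);
  double G[8][3];
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j)
      for (int k = 0; k < q; ++k) {
        double xi[3] = {gx[i], gx[j], gx[k]};
        double w = gw[i] * gw[j] * gw[k];
        basis_grad(xi, G);
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b)
            K(a, b) += w * (G[a][0] * G[b][0] + G[a][1] * G[b][1] +
                            G[a][2] * G[b][2]);
      }
  return K;
}

// face coupling matrices for a face in positive direction `axis`
// (element e owns the face at xi_axis = 1, neighbour f at xi_axis = 0);
// all on the unit reference cell with the local normal derivative d/dxi_axis
struct FaceRef {
  double Mee[8][8], Mef[8][8], Mff[8][8];
  double Dee[8][8], Def[8][8], Dfe[8][8], Dff[8][8];
};

static void face_ref(int axis, int q, FaceRef& R) {
  std::memset(&R, 0, sizeof(FaceRef));
  FaceQuad fe = face_quad(axis, 1.0, q);
  int nq = (int)fe.w.size();
  for (int p = 0; p < nq; ++p) {
    const double* xe = &fe.xi[3 * p];
    double xf[3] = {xe[0], xe[1], xe[2]};
    xf[axis] = 0.0;
    double Ne[8], Nf[8], Ge[8][3], Gf[8][3];
    basis_val(xe, Ne); basis_val(xf, Nf);
    basis_grad(xe, Ge); basis_grad(xf, Gf);
    double w = fe.w[p];
    for (int i = 0; i < 8; ++i)
      for (int j = 0; j < 8; ++j) {
        R.Mee[i][j] += w * Ne[i] * Ne[j];
        R.Mef[i][j] += w * Ne[i] * Nf[j];
        R.Mff[i][j] += w * Nf[i] * Nf[j];
        R.Dee[i][j] += w * Ne[i] * Ge[j][axis];
        R.Def[i][j] += w * Ne[i] * Gf[j][axis];
        R.Dfe[i][j] += w * Nf[i] * Ge[j][axis];
        R.Dff[i][j] += w * Nf[i] * Gf[j][axis];
      }
  }
}

// ---------------------------------------------------------------------------
// SIPG stiffness assembly (CSC arrays of a symmetric sparse matrix)
// ---------------------------------------------------------------------------

// neighbors: nelem x 6 (0-based element ids, -1 if absent), direction order
// (-x, +x, -y, +y, -z, +z)
// [[Rcpp::export]]
List cpp_dg_stiffness(NumericVector sigma, double h, double eta,
                      IntegerMatrix neighbors) {
  int nelem = sigma.size();
  NumericMatrix Kref = cpp_ref_stiffness(2);
  FaceRef FR[3];
  for (int a = 0; a < 3; ++a) face_ref(a, 2, FR[a]);

  // coupled element lists (sorted, self included)
  std::vector<int> cpl;          // concatenated lists
  std::vector<int> cstart(nelem + 1, 0);
  cpl.reserve((size_t)nelem * 7);
  for (int e = 0; e < nelem; ++e) {
    int tmp[7]; int nc = 0;
    tmp[nc++] = e;
    for (int d = 0; d < 6; ++d) {
      int f = neighbors(e, d);
      if (f >= 0) tmp[nc++] = f;
    }
    std::sort(tmp, tmp + nc);
    cstart[e + 1] = cstart[e] + nc;
    for (int k = 0; k < nc; ++k) cpl.push_back(tmp[k]);
  }

  int ndof = 8 * nelem;
  IntegerVector p(ndof + 1);
  // row r of element e has 8 * ncpl(e) entries
  for (int e = 0; e < nelem; ++e) {
    int nc = cstart[e + 1] - cstart[e];
    for (int r = 0; r < 8; ++r) p[8 * e + r + 1] = p[8 * e + r] + 8 * nc;
  }
  size_t nnz = (size_t)p[ndof];
  IntegerVector ivec(nnz);
  NumericVector xvec(nnz);
  double* xs = REAL(xvec);
  // column indices (structure identical for the 8 rows of an element)
  for (int e = 0; e < nelem; ++e) {
    for (int r = 0; r < 8; ++r) {
      size_t off = (size_t)p[8 * e + r];
      for (int k = cstart[e]; k < cstart[e + 1]; ++k) {
        int c = cpl[k];
        for (int j = 0; j < 8; ++j) ivec[off++] = 8 * c + j;
      }
    }
  }

  // position of entry (row = 8 e + r, col = 8 c + j)
  auto pos = [&](int e, int r, int c, int j) -> size_t {
    int rank = -1;
    for (int k = cstart[e]; k < cstart[e + 1]; ++k)
      if (cpl[k] == c) { rank = k - cstart[e]; break; }
    return (size_t)p[8 * e + r] + 8 * (size_t)rank + j;
  };

  // volume terms
  for (int e = 0; e < nelem; ++e) {
    double c = sigma[e] * h;
    for (int r = 0; r < 8; ++r)
      for (int j = 0; j < 8; ++j)
        xs[pos(e, r, e, j)] += c * Kref(r, j);
  }

  // face terms: loop positive directions so each internal face is seen once
  for (int e = 0; e < nelem; ++e) {
    for (int a = 0; a < 3; ++a) {
      int f = neighbors(e, 2 * a + 1);
      if (f < 0) continue;
      const FaceRef& R = FR[a];
      double se = sigma[e], sf = sigma[f];
      double gam = se * sf / (se + sf);       // = w_e s_e = w_f s_f
      double shat = 2.0 * gam;                // harmonic mean
      double pen = eta * shat * h;            // (eta shat / h) * h^2
      double gh = gam * h;
      for (int i = 0; i < 8; ++i)
        for (int j = 0; j < 8; ++j) {
          double vee = -gh * (R.Dee[i][j] + R.Dee[j][i]) + pen * R.Mee[i][j];
          double vef = -gh * R.Def[i][j] + gh * R.Dfe[j][i] - pen * R.Mef[i][j];
          double vff = gh * (R.Dff[i][j] + R.Dff[j][i]) + pen * R.Mff[i][j];
          xs[pos(e, i, e, j)] += vee;
          xs[pos(e, i, f, j)] += vef;
          xs[pos(f, j, e, i)] += vef;  // transpose block
          xs[pos(f, i, f, j)] += vff;
        }
    }
  }

  return List::create(Named("p") = p, Named("i") = ivec,
                      Named("x") = xvec, Named("ndof") = ndof);
}

// inverses of the 8x8 diagonal blocks of the SIPG matrix (block-Jacobi
// smoother); returns CSC triplet arrays of the block-diagonal inverse
// [[Rcpp::export]]
List cpp_dg_block_inverse(IntegerVector p, IntegerVector iv, NumericVector x,
                          int nelem) {
  NumericVector xs((size_t)nelem * 64);
  for (int e = 0; e < nelem; ++e) {
    double A[8][16];  // augmented [block | I]
    for (int r = 0; r < 8; ++r) {
      int row = 8 * e + r;
      double vals[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (int k = p[row]; k < p[row + 1]; ++k) {
        int c = iv[k];
        if (c >= 8 * e && c < 8 * e + 8) vals[c - 8 * e] = x[k];
      }
      for (int c = 0; c < 8; ++c) {
        A[r][c] = vals[c];
        A[r][8 + c] = (r == c) ? 1.0 : 0.0;
      }
    }
    // Gauss-Jordan with partial pivoting
    for (int col = 0; col < 8; ++col) {
      int piv = col;
      for (int r = col + 1; r < 8; ++r)
        if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
      if (piv != col)
        for (int c = 0; c < 16; ++c) std::swap(A[col][c], A[piv][c]);
      double d = A[col][col];
      if (d == 0.0) stop("singular diagonal block in SIPG matrix");
      for (int c = 0; c < 16; ++c) A[col][c] /= d;
      for (int r = 0; r < 8; ++r) {
        if (r == col) continue;
        double f = A[r][col];
        if (f == 0.0) continue;
        for (int c = 0; c < 16; ++c) A[r][c] -= f * A[col][c];
      }
    }
    for (int c = 0; c < 8; ++c)
      for (int r = 0; r < 8; ++r)
        xs[(size_t)e * 64 + 8 * c + r] = A[r][8 + c];  // column-major
  }
  return List::create(Named("x") = xs);
}

// ---------------------------------------------------------------------------
// Subtraction right-hand sides
// ---------------------------------------------------------------------------

// shared boundary-term accumulation; dof index of (e, i) given by idx(e, i)
template <typename IDX>
static void rhs_boundary(NumericVector& rhs, const NumericMatrix& eori,
                         double h, double sinf, const double* r0,
                         const double* M, const IntegerMatrix& bfaces,
                         int qface, IDX idx) {
  int nb = bfaces.nrow();
  for (int b = 0; b < nb; ++b) {
    int e = bfaces(b, 0), a = bfaces(b, 1), s = bfaces(b, 2);
    FaceQuad fq = face_quad(a, s > 0 ? 1.0 : 0.0, qface);
    int nq = (int)fq.w.size();
    for (int pqi = 0; pqi < nq; ++pqi) {
      const double* xi = &fq.xi[3 * pqi];
      double x[3] = {eori(e, 0) + h * xi[0], eori(e, 1) + h * xi[1],
                     eori(e, 2) + h * xi[2]};
      double g[3];
      grad_uinf(x, r0, M, sinf, g);
      double gn = s * g[a];
      double N[8];
      basis_val(xi, N);
      double c = fq.w[pqi] * h * h * sinf * gn;
      for (int i = 0; i < 8; ++i) rhs[idx(e, i)] -= c * N[i];
    }
  }
}

template <typename IDX>
static void rhs_volume(NumericVector& rhs, const NumericMatrix& eori,
                       const NumericVector& sigma, double h, double sinf,
                       const double* r0, const double* M, int qvol, IDX idx) {
  std::vector<double> gx, gw;
  gauss01(qvol, gx, gw);
  int nelem = eori.nrow();
  double G[8][3];
  for (int e = 0; e < nelem; ++e) {
    double scorr = sigma[e] - sinf;
    if (scorr == 0.0) continue;
    for (int i = 0; i < qvol; ++i)
      for (int j = 0; j < qvol; ++j)
        for (int k = 0; k < qvol; ++k) {
          double xi[3] = {gx[i], gx[j], gx[k]};
          double w = gw[i] * gw[j] * gw[k];
          double x[3] = {eori(e, 0) + h * xi[0], eori(e, 1) + h * xi[1],
                         eori(e, 2) + h * xi[2]};
          double g[3];
          grad_uinf(x, r0, M, sinf, g);
          basis_grad(xi, G);
          double c = w * h * h * scorr;  // h^3 * (1/h) gradient scale
          for (int b = 0; b < 8; ++b)
            rhs[idx(e, b)] -=
              c * (g[0] * G[b][0] + g[1] * G[b][1] + g[2] * G[b][2]);
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_cg_rhs(NumericMatrix eori, IntegerMatrix elems,
                         NumericVector sigma, double h, double sinf,
                         NumericVector r0, NumericVector M,
                         IntegerMatrix bfaces, int qvol, int qface,
                         int nvert) {
  NumericVector rhs(nvert);
  auto idx = [&](int e, int i) { return elems(e, i); };
  rhs_volume(rhs, eori, sigma, h, sinf, r0.begin(), M.begin(), qvol, idx);
  rhs_boundary(rhs, eori, h, sinf, r0.begin(), M.begin(), bfaces, qface, idx);
  return rhs;
}

// ifaces: nint x 3 (e, f, axis), f the +axis neighbour of e (0-based)
// [[Rcpp::export]]
NumericVector cpp_dg_rhs(NumericMatrix eori, NumericVector sigma, double h,
                         double sinf, NumericVector r0, NumericVector M,
                         IntegerMatrix bfaces, IntegerMatrix ifaces, int qvol,
                         int qface) {
  int nelem = eori.nrow();
  NumericVector rhs(8 * nelem);
  auto idx = [&](int e, int i) { return 8 * e + i; };
  rhs_volume(rhs, eori, sigma, h, sinf, r0.begin(), M.begin(), qvol, idx);
  rhs_boundary(rhs, eori, h, sinf, r0.begin(), M.begin(), bfaces, qface, idx);

  // skeleton term: + int_Gamma {sigma_corr grad u_inf} . [[v]]
  int nint = ifaces.nrow();
  for (int k = 0; k < nint; ++k) {
    int e = ifaces(k, 0), f = ifaces(k, 1), a = ifaces(k, 2);
    double se = sigma[e], sf = sigma[f];
    double sce = se - sinf, scf = sf - sinf;
    if (sce == 0.0 && scf == 0.0) continue;
    double we = sf / (se + sf), wf = se / (se + sf);
    double wq = we * sce + wf * scf;
    FaceQuad fe = face_quad(a, 1.0, qface);
    int nq = (int)fe.w.size();
    for (int pqi = 0; pqi < nq; ++pqi) {
      const double* xe = &fe.xi[3 * pqi];
      double xf[3] = {xe[0], xe[1], xe[2]};
      xf[a] = 0.0;
      double x[3] = {eori(e, 0) + h * xe[0], eori(e, 1) + h * xe[1],
                     eori(e, 2) + h * xe[2]};
      double g[3];
      grad_uinf(x, r0.begin(), M.begin(), sinf, g);
      double qn = wq * g[a];  // normal e -> f is +axis a
      double Ne[8], Nf[8];
      basis_val(xe, Ne); basis_val(xf, Nf);
      double c = fe.w[pqi] * h * h * qn;
      for (int i = 0; i < 8; ++i) {
        rhs[idx(e, i)] += c * Ne[i];
        rhs[idx(f, i)] -= c * Nf[i];
      }
    }
  }
  return rhs;
}

// ---------------------------------------------------------------------------
// Element-wise charge balance of the discrete flux
// ---------------------------------------------------------------------------

// conservative = true : skeleton flux {sigma grad u} . n - eta shat/h [[u]] . n
// conservative = false: one-sided nodal flux sigma_K grad u_K . n
// Returns, for each element K,
//   sum_int int( j.n_K + {s_corr grad u_inf}.n_K ) - sum_bnd int( sinf grad u_inf . n )
// which vanishes (up to solver tolerance) for the conservative flux.
// [[Rcpp::export]]
NumericVector cpp_dg_balance(NumericMatrix eori, NumericVector sigma,
                             double h, double eta, IntegerMatrix neighbors,
                             NumericVector u, double sinf, NumericVector r0,
                             NumericVector M, int qface, bool conservative) {
  int nelem = eori.nrow();
  NumericVector bal(nelem);
  for (int e = 0; e < nelem; ++e) {
    double res = 0.0;
    for (int d = 0; d < 6; ++d) {
      int a = d / 2;
      int s = (d % 2 == 1) ? 1 : -1;
      int f = neighbors(e, d);
      double ce = (s > 0) ? 1.0 : 0.0;
      FaceQuad fq = face_quad(a, ce, qface);
      int nq = (int)fq.w.size();
      for (int pqi = 0; pqi < nq; ++pqi) {
        const double* xe = &fq.xi[3 * pqi];
        double x[3] = {eori(e, 0) + h * xe[0], eori(e, 1) + h * xe[1],
                       eori(e, 2) + h * xe[2]};
        double g[3];
        grad_uinf(x, r0.begin(), M.begin(), sinf, g);
        double w = fq.w[pqi] * h * h;
        if (f < 0) {
          res -= w * sinf * (s * g[a]);
          continue;
        }
        double se = sigma[e], sf = sigma[f];
        double sce = se - sinf, scf = sf - sinf;
        double Ge[8][3];
        basis_grad(xe, Ge);
        double due = 0.0, ue = 0.0;
        double Ne[8];
        basis_val(xe, Ne);
        for (int i = 0; i < 8; ++i) {
          due += u[8 * e + i] * Ge[i][a];
          ue += u[8 * e + i] * Ne[i];
        }
        due *= s / h;  // physical normal derivative (outward)
        double flux, upart;
        if (conservative) {
          double xf[3] = {xe[0], xe[1], xe[2]};
          xf[a] = 1.0 - ce;
          double Gf[8][3], Nf[8];
          basis_grad(xf, Gf); basis_val(xf, Nf);
          double duf = 0.0, uf = 0.0;
          for (int i = 0; i < 8; ++i) {
            duf += u[8 * f + i] * Gf[i][a];
            uf += u[8 * f + i] * Nf[i];
          }
          duf *= s / h;
          double gam = se * sf / (se + sf);
          double shat = 2.0 * gam;
          double we = sf / (se + sf), wf = se / (se + sf);
          flux = gam * (due + duf) - eta * shat / h * (ue - uf);
          upart = (we * sce + wf * scf) * (s * g[a]);
        } else {
          flux = se * due;
          upart = sce * (s * g[a]);
        }
        res += w * (flux + upart);
      }
    }
    bal[e] = res;
  }
  return bal;
}

// ---------------------------------------------------------------------------
// Conservative skeleton flux at face centroids (RT0 degrees of freedom)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conservative_flux(NumericMatrix eori, NumericVector sigma,
                                    double h, double eta, IntegerMatrix ifaces,
                                    NumericVector u) {
  int nint = ifaces.nrow();
  NumericVector alpha(nint);
  for (int k = 0; k < nint; ++k) {
    int e = ifaces(k, 0), f = ifaces(k, 1), a = ifaces(k, 2);
    double xe[3] = {0.5, 0.5, 0.5}, xf[3] = {0.5, 0.5, 0.5};
    xe[a] = 1.0; xf[a] = 0.0;
    double Ge[8][3], Gf[8][3], Ne[8], Nf[8];
    basis_grad(xe, Ge); basis_grad(xf, Gf);
    basis_val(xe, Ne); basis_val(xf, Nf);
    double due = 0.0, duf = 0.0, ue = 0.0, uf = 0.0;
    for (int i = 0; i < 8; ++i) {
      due += u[8 * e + i] * Ge[i][a];
      duf += u[8 * f + i] * Gf[i][a];
      ue += u[8 * e + i] * Ne[i];
      uf += u[8 * f + i] * Nf[i];
    }
    due /= h; duf /= h;
    double se = sigma[e], sf = sigma[f];
    double gam = se * sf / (se + sf);
    double shat = 2.0 * gam;
    alpha[k] = gam * (due + duf) - eta * shat / h * (ue - uf);
  }
  return alpha;
}

// ---------------------------------------------------------------------------
// Biot-Savart integration of nodal fluxes sigma grad u_h
// ---------------------------------------------------------------------------

// basis_kind: 0 = CG (columns indexed by elems), 1 = DG (8 e + i)
// [[Rcpp::export]]
NumericMatrix cpp_bs_nodal_matrix(NumericMatrix eori, IntegerMatrix elems,
                                  NumericVector sigma, double h,
                                  NumericMatrix sensors, int q,
                                  int basis_kind, int ndof) {
  int nelem = eori.nrow(), ns = sensors.nrow();
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  NumericMatrix S(3 * ns, ndof);
  double G[8][3];
  for (int e = 0; e < nelem; ++e) {
    double se = sigma[e];
    for (int i = 0; i < q; ++i)
      for (int j = 0; j < q; ++j)
        for (int k = 0; k < q; ++k) {
          double xi[3] = {gx[i], gx[j], gx[k]};
          double w = gw[i] * gw[j] * gw[k] * h * h * se;  // h^3 / h
          double x[3] = {eori(e, 0) + h * xi[0], eori(e, 1) + h * xi[1],
                         eori(e, 2) + h * xi[2]};
          basis_grad(xi, G);
          for (int n = 0; n < ns; ++n) {
            double d0 = sensors(n, 0) - x[0], d1 = sensors(n, 1) - x[1],
              d2 = sensors(n, 2) - x[2];
            double r2 = d0 * d0 + d1 * d1 + d2 * d2;
            double r3 = r2 * std::sqrt(r2);
            double k0 = d0 / r3, k1 = d1 / r3, k2 = d2 / r3;
            for (int b = 0; b < 8; ++b) {
              int col = (basis_kind == 1) ? 8 * e + b : elems(e, b);
              double c = -MU0_4PI * w;
              S(3 * n + 0, col) += c * (G[b][1] * k2 - G[b][2] * k1);
              S(3 * n + 1, col) += c * (G[b][2] * k0 - G[b][0] * k2);
              S(3 * n + 2, col) += c * (G[b][0] * k1 - G[b][1] * k0);
            }
          }
        }
  }
  return S;
}

// [[Rcpp::export]]
NumericMatrix cpp_bs_nodal_apply(NumericMatrix eori, IntegerMatrix elems,
                                 NumericVector sigma, double h,
                                 NumericMatrix sensors, int q, int basis_kind,
                                 NumericVector coef) {
  int nelem = eori.nrow(), ns = sensors.nrow();
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  NumericMatrix B(ns, 3);
  double G[8][3];
  for (int e = 0; e < nelem; ++e) {
    double se = sigma[e];
    double ce[8];
    for (int b = 0; b < 8; ++b)
      ce[b] = (basis_kind == 1) ? coef[8 * e + b] : coef[elems(e, b)];
    for (int i = 0; i < q; ++i)
      for (int j = 0; j < q; ++j)
        for (int k = 0; k < q; ++k) {
          double xi[3] = {gx[i], gx[j], gx[k]};
          double w = gw[i] * gw[j] * gw[k] * h * h * se;
          double x[3] = {eori(e, 0) + h * xi[0], eori(e, 1) + h * xi[1],
                         eori(e, 2) + h * xi[2]};
          basis_grad(xi, G);
          double v0 = 0, v1 = 0, v2 = 0;
          for (int b = 0; b < 8; ++b) {
            v0 += ce[b] * G[b][0];
            v1 += ce[b] * G[b][1];
            v2 += ce[b] * G[b][2];
          }
          for (int n = 0; n < ns; ++n) {
            double d0 = sensors(n, 0) - x[0], d1 = sensors(n, 1) - x[1],
              d2 = sensors(n, 2) - x[2];
            double r2 = d0 * d0 + d1 * d1 + d2 * d2;
            double r3 = r2 * std::sqrt(r2);
            double k0 = d0 / r3, k1 = d1 / r3, k2 = d2 / r3;
            double c = -MU0_4PI * w;
            B(n, 0) += c * (v1 * k2 - v2 * k1);
            B(n, 1) += c * (v2 * k0 - v0 * k2);
            B(n, 2) += c * (v0 * k1 - v1 * k0);
          }
        }
  }
  return B;
}

// ---------------------------------------------------------------------------
// Biot-Savart moments of RT0 basis functions (tent profile across the face)
// ---------------------------------------------------------------------------

static void rt0_face_accum(double* col, int ncolstride, const NumericMatrix& eori,
                           double h, int e, int a, double sgn,
                           const double* xbar, const NumericMatrix& sensors,
                           const std::vector<double>& gx,
                           const std::vector<double>& gw, double scale) {
  // integrate (1 - |(x - xbar) . n| / h) * (n x kernel) over element e;
  // n = sgn * e_a; scale multiplies the accumulated contribution
  int q = (int)gx.size();
  int ns = sensors.nrow();
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j)
      for (int k = 0; k < q; ++k) {
        double xi[3] = {gx[i], gx[j], gx[k]};
        double w = gw[i] * gw[j] * gw[k] * h * h * h;
        double x[3] = {eori(e, 0) + h * xi[0], eori(e, 1) + h * xi[1],
                       eori(e, 2) + h * xi[2]};
        double proj = (x[a] - xbar[a]) * sgn;
        double tent = 1.0 - std::fabs(proj) / h;
        if (tent <= 0.0) continue;
        double n0 = (a == 0) ? sgn : 0.0, n1 = (a == 1) ? sgn : 0.0,
          n2 = (a == 2) ? sgn : 0.0;
        for (int n = 0; n < ns; ++n) {
          double d0 = sensors(n, 0) - x[0], d1 = sensors(n, 1) - x[1],
            d2 = sensors(n, 2) - x[2];
          double r2 = d0 * d0 + d1 * d1 + d2 * d2;
          double r3 = r2 * std::sqrt(r2);
          double k0 = d0 / r3, k1 = d1 / r3, k2 = d2 / r3;
          double c = -MU0_4PI * w * tent * scale;
          col[(3 * n + 0) * ncolstride] += c * (n1 * k2 - n2 * k1);
          col[(3 * n + 1) * ncolstride] += c * (n2 * k0 - n0 * k2);
          col[(3 * n + 2) * ncolstride] += c * (n0 * k1 - n1 * k0);
        }
      }
}

// columns: internal faces first (normal +axis from e to f), then boundary
// faces (outward normal)
// [[Rcpp::export]]
NumericMatrix cpp_rt0_moment_matrix(NumericMatrix eori, double h,
                                    IntegerMatrix ifaces, IntegerMatrix bfaces,
                                    NumericMatrix sensors, int q) {
  int nint = ifaces.nrow(), nb = bfaces.nrow(), ns = sensors.nrow();
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  NumericMatrix Smat(3 * ns, nint + nb);
  for (int k = 0; k < nint; ++k) {
    int e = ifaces(k, 0), f = ifaces(k, 1), a = ifaces(k, 2);
    double xbar[3] = {eori(e, 0) + 0.5 * h, eori(e, 1) + 0.5 * h,
                      eori(e, 2) + 0.5 * h};
    xbar[a] = eori(e, a) + h;
    double* col = &Smat(0, k);
    rt0_face_accum(col, 1, eori, h, e, a, 1.0, xbar, sensors, gx, gw, 1.0);
    rt0_face_accum(col, 1, eori, h, f, a, 1.0, xbar, sensors, gx, gw, 1.0);
  }
  for (int b = 0; b < nb; ++b) {
    int e = bfaces(b, 0), a = bfaces(b, 1), s = bfaces(b, 2);
    double xbar[3] = {eori(e, 0) + 0.5 * h, eori(e, 1) + 0.5 * h,
                      eori(e, 2) + 0.5 * h};
    xbar[a] = eori(e, a) + (s > 0 ? h : 0.0);
    double* col = &Smat(0, nint + b);
    rt0_face_accum(col, 1, eori, h, e, a, (double)s, xbar, sensors, gx, gw, 1.0);
  }
  return Smat;
}

// [[Rcpp::export]]
NumericMatrix cpp_rt0_apply(NumericMatrix eori, double h, IntegerMatrix ifaces,
                            IntegerMatrix bfaces, NumericMatrix sensors, int q,
                            NumericVector alpha_int, NumericVector alpha_bnd) {
  int nint = ifaces.nrow(), nb = bfaces.nrow(), ns = sensors.nrow();
  std::vector<double> gx, gw;
  gauss01(q, gx, gw);
  NumericVector acc(3 * ns);
  for (int k = 0; k < nint; ++k) {
    if (alpha_int[k] == 0.0) continue;
    int e = ifaces(k, 0), f = ifaces(k, 1), a = ifaces(k, 2);
    double xbar[3] = {eori(e, 0) + 0.5 * h, eori(e, 1) + 0.5 * h,
                      eori(e, 2) + 0.5 * h};
    xbar[a] = eori(e, a) + h;
    rt0_face_accum(acc.begin(), 1, eori, h, e, a, 1.0, xbar, sensors, gx, gw,
                   alpha_int[k]);
    rt0_face_accum(acc.begin(), 1, eori, h, f, a, 1.0, xbar, sensors, gx, gw,
                   alpha_int[k]);
  }
  for (int b = 0; b < nb; ++b) {
    if (alpha_bnd[b] == 0.0) continue;
    int e = bfaces(b, 0), a = bfaces(b, 1), s = bfaces(b, 2);
    double xbar[3] = {eori(e, 0) + 0.5 * h, eori(e, 1) + 0.5 * h,
                      eori(e, 2) + 0.5 * h};
    xbar[a] = eori(e, a) + (s > 0 ? h : 0.0);
    rt0_face_accum(acc.begin(), 1, eori, h, e, a, (double)s, xbar, sensors,
                   gx, gw, alpha_bnd[b]);
  }
  NumericMatrix B(ns, 3);
  for (int n = 0; n < ns; ++n)
    for (int c = 0; c < 3; ++c) B(n, c) = acc[3 * n + c];
  return B;
}
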