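// ADMM solver for the electrode-current quadratic subproblem
//
//   minimize    0.5 * s' H s  -  c' s
//   subject to  sum(s) = 0,  ||s||_1 <= Imax
//
// H is a small (m x m) symmetric positive semidefinite matrix. The
// constraint set D = {sum = 0} \cap {L1 ball} is handled by Dykstra's
// alternating projections (both individual projections are exact). The
// returned point is the projected iterate, so it lies in D to projection
// tolerance; callers re-centre and re-scale for exact feasibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// in-place dense Cholesky of A (n x n, column major), lower triangle
static bool chol_inplace(std::vector<double>& A, int n) {
  for (int j = 0; j < n; ++j) {
    double d = A[j + j * n];
    for (int k = 0; k < j; ++k) d -= A[j + k * n] * A[j + k * n];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j + j * n] = d;
    for (int i = j + 1; i < n; ++i) {
      double v = A[i + j * n];
      for (int k = 0; k < j; ++k) v -= A[i + k * n] * A[j + k * n];
      A[i + j * n] = v / d;
    }
  }
  return true;
}

// solve L L' x = b with L lower triangular from chol_inplace
static void chol_solve(const std::vector<double>& L, int n,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) {
    double v = b[i];
    for (int k = 0; k < i; ++k) v -= L[i + k * n] * y[k];
    y[i] = v / L[i + i * n];
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = y[i];
    for (int k = i + 1; k < n; ++k) v -= L[k + i * n] * x[k];
    x[i] = v / L[i + i * n];
  }
}

// Euclidean projection onto the L1 ball of radius r (r > 0)
static void proj_l1(std::vector<double>& v, double r) {
  int n = (int)v.size();
  double a = 0.0;
  for (int i = 0; i < n; ++i) a += std::fabs(v[i]);
  if (a <= r) return;
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) u[i] = std::fabs(v[i]);
  std::sort(u.begin(), u.end(), std::greater<double>());
  double csum = 0.0, tau = 0.0;
  for (int k = 0; k < n; ++k) {
    csum += u[k];
    double t = (csum - r) / (k + 1);
    if (k == n - 1 || u[k + 1] <= t) { tau = t; break; }
  }
  for (int i = 0; i < n; ++i) {
    double mag = std::fabs(v[i]) - tau;
    v[i] = (mag > 0.0) ? ((v[i] > 0) ? mag : -mag) : 0.0;
  }
}

static void proj_zerosum(std::vector<double>& v) {
  double mu = 0.0;
  int n = (int)v.size();
  for (int i = 0; i < n; ++i) mu += v[i];
  mu /= n;
  for (int i = 0; i < n; ++i) v[i] -= mu;
}

// Dykstra's algorithm: projection onto {sum = 0} \cap {||.||_1 <= r}
static void proj_D(std::vector<double>& x, double r, int max_sweeps,
                   double tol) {
  int n = (int)x.size();
  std::vector<double> p(n, 0.0), q(n, 0.0), y(n), xprev(n);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    xprev = x;
    for (int i = 0; i < n; ++i) y[i] = x[i] + p[i];
    std::vector<double> y1 = y;
    proj_zerosum(y1);
    for (int i = 0; i < n; ++i) p[i] = y[i] - y1[i];
    for (int i = 0; i < n; ++i) y[i] = y1[i] + q[i];
    std::vector<double> y2 = y;
    proj_l1(y2, r);
    for (int i = 0; i < n; ++i) q[i] = y[i] - y2[i];
    x = y2;
    double diff = 0.0;
    for (int i = 0; i < n; ++i) diff = std::max(diff, std::fabs(x[i] - xprev[i]));
    if (diff < tol) break;
  }
  // leave exactly inside both sets: re-centre, then shrink radially
  proj_zerosum(x);
  double a = 0.0;
  for (int i = 0; i < n; ++i) a += std::fabs(x[i]);
  if (a > r && a > 0.0) {
    double sc = r / a;
    for (int i = 0; i < n; ++i) x[i] *= sc;
  }
}

// power iteration estimates of the extreme eigenvalues of H (symmetric
// PSD), used to initialize the ADMM penalty near its optimal value
static void eig_range(const NumericMatrix& H, int m, double& lo, double& hi) {
  std::vector<double> v(m), w(m);
  for (int i = 0; i < m; ++i) v[i] = 1.0 / std::sqrt((double)m);
  hi = 0.0;
  for (int it = 0; it < 30; ++it) {
    double nrm = 0.0;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += H(i, j) * v[j];
      w[i] = acc; nrm += acc * acc;
    }
    nrm = std::sqrt(nrm);
    if (nrm <= 0.0) { hi = 0.0; break; }
    hi = nrm;
    for (int i = 0; i < m; ++i) v[i] = w[i] / nrm;
  }
  // smallest eigenvalue via power iteration on (hi*I - H)
  double shift = hi * 1.0000001 + 1e-30;
  for (int i = 0; i < m; ++i) v[i] = (i % 2 ? -1.0 : 1.0) / std::sqrt((double)m);
  double mu = 0.0;
  for (int it = 0; it < 30; ++it) {
    double nrm = 0.0;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += H(i, j) * v[j];
      w[i] = shift * v[i] - acc; nrm += w[i] * w[i];
    }
    nrm = std::sqrt(nrm);
    if (nrm <= 0.0) { mu = shift; break; }
    mu = nrm;
    for (int i = 0; i < m; ++i) v[i] = w[i] / nrm;
  }
  lo = std::max(shift - mu, 0.0);
}

// [[Rcpp::export(name = ".polytope_qp")]]
List polytope_qp(NumericMatrix H, NumericVector c, double Imax,
                 NumericVector s0, int max_iter = 20000,
                 double tol = 1e-12, Nullable<NumericVector> u0 = R_NilValue) {
  int m = H.nrow();
  std::vector<double> s(m), z(m), u(m, 0.0), rhs(m), zold(m);
  for (int i = 0; i < m; ++i) z[i] = s0[i];
  proj_D(z, Imax, 500, 1e-15);
  if (u0.isNotNull()) {
    NumericVector uu(u0);
    if ((int)uu.size() == m) for (int i = 0; i < m; ++i) u[i] = uu[i];
  }

  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i)
      if (!std::isfinite(H(i, j)))
        stop("non-finite entries in quadratic subproblem matrix");
  double elo, ehi;
  eig_range(H, m, elo, ehi);
  double rho0 = std::sqrt(std::max(elo, 1e-8 * ehi + 1e-12) *
                          std::max(ehi, 1e-12));
  rho0 = std::max(rho0, 1e-8);
  double rho = rho0;
  const double rho_min = rho0 * 1e-6, rho_max = rho0 * 1e6;

  std::vector<double> F;
  auto factor = [&](double r) {
    F.assign(m * m, 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i)
        F[i + j * m] = H(i, j) + ((i == j) ? r : 0.0);
    if (!chol_inplace(F, m)) stop("quadratic subproblem matrix not positive definite");
  };
  factor(rho);

  int it = 0;
  double rnorm = 0.0, dnorm = 0.0;
  const double eps_abs = tol, eps_rel = 1e-8;
  const double relax = 1.6;  // over-relaxation
  for (it = 0; it < max_iter; ++it) {
    for (int i = 0; i < m; ++i) rhs[i] = c[i] + rho * (z[i] - u[i]);
    chol_solve(F, m, rhs, s);
    zold = z;
    for (int i = 0; i < m; ++i)
      z[i] = relax * s[i] + (1.0 - relax) * zold[i] + u[i];
    proj_D(z, Imax, 20, 1e-13 * std::max(1.0, Imax));
    for (int i = 0; i < m; ++i)
      u[i] += relax * s[i] + (1.0 - relax) * zold[i] - z[i];

    double sn = 0.0, zn = 0.0, un = 0.0;
    rnorm = 0.0; dnorm = 0.0;
    for (int i = 0; i < m; ++i) {
      rnorm += (s[i] - z[i]) * (s[i] - z[i]);
      dnorm += (z[i] - zold[i]) * (z[i] - zold[i]);
      sn += s[i] * s[i]; zn += z[i] * z[i]; un += u[i] * u[i];
    }
    rnorm = std::sqrt(rnorm);
    dnorm = rho * std::sqrt(dnorm);
    double eps_pri = std::sqrt((double)m) * eps_abs +
      eps_rel * std::max(std::sqrt(sn), std::sqrt(zn));
    double eps_dual = std::sqrt((double)m) * eps_abs +
      eps_rel * rho * std::sqrt(un);
    if (rnorm <= eps_pri && dnorm <= eps_dual) break;
    if ((it + 1) % 10 == 0) {
      if (rnorm > 10.0 * dnorm / rho && rho < rho_max) {
        rho *= 2.0; factor(rho);
        for (int i = 0; i < m; ++i) u[i] *= 0.5;
      } else if (dnorm / rho > 10.0 * rnorm && rho > rho_min) {
        rho *= 0.5; factor(rho);
        for (int i = 0; i < m; ++i) u[i] *= 2.0;
      }
    }
  }

  NumericVector out(m), uout(m);
  for (int i = 0; i < m; ++i) { out[i] = z[i]; uout[i] = u[i]; }
  return List::create(_["s"] = out, _["u"] = uout,
                      _["iterations"] = it + 1,
                      _["primal_residual"] = rnorm,
                      _["dual_residual"] = dnorm);
}
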