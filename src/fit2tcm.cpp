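// Voxel-wise weighted nonlinear least-squares for the two-tissue-compartment
// model. The tissue model is linear in k1, so k1 is profiled out analytically
// and a bounded Nelder-Mead search runs over (k2, k3, k4) (or (k2, k3) with
// k4 fixed) on a sigmoid transform of the box constraints. Frame-averaged
// exponential convolutions F(alpha) are supplied as a precomputed basis and
// evaluated by cubic Hermite interpolation over a dense alpha grid.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct Basis {
  int na, nf;
  const double *a, *F, *D; // F, D column-major (na x nf)
};

// Hermite-interpolated row F(alpha, .) -> out[nf]
void basis_eval(const Basis& B, double alpha, double* out) {
  if (alpha <= B.a[0]) {
    for (int j = 0; j < B.nf; ++j) out[j] = B.F[(size_t)j * B.na];
    return;
  }
  if (alpha >= B.a[B.na - 1]) alpha = B.a[B.na - 1];
  int lo = 0, hi = B.na - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (B.a[mid] <= alpha) lo = mid; else hi = mid;
  }
  double h = B.a[lo + 1] - B.a[lo];
  double s = (alpha - B.a[lo]) / h;
  double s2 = s * s, s3 = s2 * s;
  double h00 = 2 * s3 - 3 * s2 + 1, h10 = s3 - 2 * s2 + s;
  double h01 = -2 * s3 + 3 * s2, h11 = s3 - s2;
  for (int j = 0; j < B.nf; ++j) {
    const double* Fc = B.F + (size_t)j * B.na;
    const double* Dc = B.D + (size_t)j * B.na;
    out[j] = h00 * Fc[lo] + h * h10 * Dc[lo] +
             h01 * Fc[lo + 1] + h * h11 * Dc[lo + 1];
  }
}

// unit-k1 model frames for (k2, k3, k4)
void unit_model(const Basis& B, double k2, double k3, double k4,
                double* m, double* f1, double* f2) {
  double S = k2 + k3 + k4;
  if (S <= 0.0) { // pure integrator: alpha = 0
    basis_eval(B, 0.0, m);
    return;
  }
  double disc = S * S - 4.0 * k2 * k4;
  if (disc < 0) disc = 0;
  double sq = std::sqrt(disc);
  double a2 = 0.5 * (S + sq);
  double a1 = (a2 > 0) ? k2 * k4 / a2 : 0.0; // product of roots, stable
  if (a2 - a1 < 1e-12) a2 = a1 + 1e-12;
  double den = a2 - a1;
  double B1 = (k3 + k4 - a1) / den;
  double B2 = (a2 - k3 - k4) / den;
  basis_eval(B, a1, f1);
  basis_eval(B, a2, f2);
  for (int j = 0; j < B.nf; ++j) m[j] = B1 * f1[j] + B2 * f2[j];
}

struct Problem {
  const Basis* B;
  const double *y, *w;
  int nf;
  double k1lo, k1hi;
  double fix_k4; // < 0 => free
  // bounds for the searched parameters (k2, k3 [, k4])
  double lo[3], hi[3];
  int dim;
  // scratch
  std::vector<double> m, f1, f2;
};

double inv_logit(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

double logit(double p) {
  if (p < 1e-10) p = 1e-10;
  if (p > 1 - 1e-10) p = 1 - 1e-10;
  return std::log(p / (1 - p));
}

// objective in transformed coordinates, with k1 profiled
double objective(Problem& P, const double* x, double* k_out) {
  double k[3];
  for (int d = 0; d < P.dim; ++d)
    k[d] = P.lo[d] + (P.hi[d] - P.lo[d]) * inv_logit(x[d]);
  double k2 = k[0], k3 = k[1];
  double k4 = (P.fix_k4 >= 0) ? P.fix_k4 : k[2];
  unit_model(*P.B, k2, k3, k4, P.m.data(), P.f1.data(), P.f2.data());
  double num = 0, den = 0;
  for (int j = 0; j < P.nf; ++j) {
    num += P.w[j] * P.m[j] * P.y[j];
    den += P.w[j] * P.m[j] * P.m[j];
  }
  double k1 = (den > 0) ? num / den : 0.0;
  if (k1 < P.k1lo) k1 = P.k1lo;
  if (k1 > P.k1hi) k1 = P.k1hi;
  double ss = 0;
  for (int j = 0; j < P.nf; ++j) {
    double r = P.y[j] - k1 * P.m[j];
    ss += P.w[j] * r * r;
  }
  if (k_out) { k_out[0] = k1; k_out[1] = k2; k_out[2] = k3; k_out[3] = k4; }
  return ss;
}

// Nelder-Mead (Lagarias parameters) on dim coordinates; returns best f,
// fills xbest; conv set if the function-spread tolerance was met
double nelder_mead(Problem& P, double* x0, int maxit, double ftol,
                   double step, bool* conv) {
  const int d = P.dim;
  const int np = d + 1;
  std::vector<std::vector<double>> X(np, std::vector<double>(d));
  std::vector<double> fv(np);
  for (int i = 0; i < np; ++i) {
    X[i].assign(x0, x0 + d);
    if (i > 0) X[i][i - 1] += step;
    fv[i] = objective(P, X[i].data(), nullptr);
  }
  std::vector<double> xr(d), xe(d), xc(d), cen(d);
  *conv = false;
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> ord(np);
    for (int i = 0; i < np; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    int ilo = ord[0], ihi = ord[np - 1], inh = ord[np - 2];
    if (fv[ihi] - fv[ilo] <= ftol * (std::fabs(fv[ilo]) + ftol)) {
      *conv = true;
      break;
    }
    for (int j = 0; j < d; ++j) {
      cen[j] = 0;
      for (int i = 0; i < np; ++i) if (i != ihi) cen[j] += X[i][j];
      cen[j] /= d;
    }
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - X[ihi][j]);
    double fr = objective(P, xr.data(), nullptr);
    if (fr < fv[ilo]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - X[ihi][j]);
      double fe = objective(P, xe.data(), nullptr);
      if (fe < fr) { X[ihi] = xe; fv[ihi] = fe; }
      else { X[ihi] = xr; fv[ihi] = fr; }
    } else if (fr < fv[inh]) {
      X[ihi] = xr; fv[ihi] = fr;
    } else {
      bool outside = fr < fv[ihi];
      if (outside) {
        for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (xr[j] - cen[j]);
      } else {
        for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (X[ihi][j] - cen[j]);
      }
      double fc = objective(P, xc.data(), nullptr);
      if (fc < std::min(fr, fv[ihi])) {
        X[ihi] = xc; fv[ihi] = fc;
      } else { // shrink toward best
        for (int i = 0; i < np; ++i) {
          if (i == ilo) continue;
          for (int j = 0; j < d; ++j)
            X[i][j] = X[ilo][j] + 0.5 * (X[i][j] - X[ilo][j]);
          fv[i] = objective(P, X[i].data(), nullptr);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < np; ++i) if (fv[i] < fv[best]) best = i;
  for (int j = 0; j < d; ++j) x0[j] = X[best][j];
  return fv[best];
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_model_frames(NumericVector k, NumericVector alpha,
                               NumericMatrix F, NumericMatrix D) {
  Basis B{(int)alpha.size(), F.ncol(), alpha.begin(), F.begin(), D.begin()};
  std::vector<double> m(B.nf), f1(B.nf), f2(B.nf);
  unit_model(B, k[1], k[2], k[3], m.data(), f1.data(), f2.data());
  NumericVector out(B.nf);
  for (int j = 0; j < B.nf; ++j) out[j] = k[0] * m[j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_fit_tacs(NumericMatrix tacs, NumericVector w,
                           NumericVector alpha, NumericMatrix F,
                           NumericMatrix D, NumericVector lower,
                           NumericVector upper, NumericMatrix starts,
                           double ftol, int maxit, double fix_k4) {
  const int nvox = tacs.nrow(), nf = tacs.ncol();
  if (w.size() != nf) stop("weight length must match frame count");
  Basis B{(int)alpha.size(), F.ncol(), alpha.begin(), F.begin(), D.begin()};
  if (B.nf != nf) stop("basis frame count must match TAC frame count");

  Problem P;
  P.B = &B;
  P.w = w.begin();
  P.nf = nf;
  P.k1lo = lower[0];
  P.k1hi = upper[0];
  P.fix_k4 = fix_k4;
  P.dim = (fix_k4 >= 0) ? 2 : 3;
  for (int d = 0; d < P.dim; ++d) {
    P.lo[d] = lower[d + 1];
    P.hi[d] = upper[d + 1];
  }
  P.m.resize(nf); P.f1.resize(nf); P.f2.resize(nf);

  const int nstart = starts.nrow();
  NumericMatrix out(nvox, 7); // k1 k2 k3 k4 wrss converged nstart_used
  std::vector<double> y(nf), x(3), xtry(3);
  double kbest[4];

  for (int v = 0; v < nvox; ++v) {
    for (int j = 0; j < nf; ++j) y[j] = tacs(v, j);
    P.y = y.data();
    double fbest = std::numeric_limits<double>::max();
    bool convbest = false;
    kbest[0] = kbest[1] = kbest[2] = kbest[3] = NA_REAL;
    for (int s = 0; s < nstart; ++s) {
      for (int d = 0; d < P.dim; ++d) {
        double k0 = starts(s, d);
        xtry[d] = logit((k0 - P.lo[d]) / (P.hi[d] - P.lo[d]));
      }
      bool conv1 = false, conv2 = false;
      nelder_mead(P, xtry.data(), maxit, ftol, 0.7, &conv1);
      // one restart from the incumbent with a tighter simplex
      double fs = nelder_mead(P, xtry.data(), maxit, ftol, 0.1, &conv2);
      double ks[4];
      fs = objective(P, xtry.data(), ks);
      // ties broken by lowest WRSS then lowest k4
      bool better = fs < fbest - 1e-12 * (1.0 + fbest);
      bool tied = !better && fs <= fbest + 1e-12 * (1.0 + fbest);
      if (better || (tied && ks[3] < kbest[3])) {
        fbest = fs;
        for (int j = 0; j < 4; ++j) kbest[j] = ks[j];
        convbest = conv1 || conv2;
      }
    }
    out(v, 0) = kbest[0]; out(v, 1) = kbest[1];
    out(v, 2) = kbest[2]; out(v, 3) = kbest[3];
    out(v, 4) = fbest;
    out(v, 5) = convbest ? 1.0 : 0.0;
    out(v, 6) = nstart;
    if (v % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
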