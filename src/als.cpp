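#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Baseline estimation by iteratively reweighted asymmetric least squares:
// a Whittaker smoother (second-order difference penalty) in which channels
// lying above the current fit by more than the spectrum's noise threshold
// are down-weighted to p, and all other channels keep weight 1.
//
// The noise scale is estimated once per spectrum from its second
// differences (robust MAD estimate; smooth structure cancels, narrow peaks
// are rejected by the median), so that on noisy spectra the fit runs
// through the middle of the noise band (no lower-envelope bias) while peak
// channels are excluded from the fit.
//
// Per spectrum y solves (W + lambda * D2'D2) z = W y.  The normal matrix
// is symmetric penta-diagonal, factorised by banded LDL' in O(n) per
// iteration.
//
// Y: n_channels x n_spectra (spectra in columns).
// [[Rcpp::export(name = ".als_baseline_cpp")]]
List als_baseline_cpp(NumericMatrix Y, double lambda, double p,
                      int maxit, double tol, int dilate) {
  const int n = Y.nrow(), m = Y.ncol();
  if (n < 4) stop("spectra must have at least 4 channels");
  if (lambda <= 0) stop("lambda must be positive");
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)");

  NumericMatrix Z(n, m);
  IntegerVector iters(m);
  LogicalVector conv(m);

  // band diagonals of D2'D2 (rows of D2 are [1, -2, 1])
  std::vector<double> a0(n, 0.0), a1(n, 0.0), a2(n, 0.0);
  const double c[3] = {1.0, -2.0, 1.0};
  for (int r = 0; r + 2 < n; ++r) {
    for (int i = 0; i < 3; ++i) {
      a0[r + i] += c[i] * c[i];
      if (i + 1 < 3) a1[r + i] += c[i] * c[i + 1];
      if (i + 2 < 3) a2[r + i] += c[i] * c[i + 2];
    }
  }

  std::vector<double> w(n), d(n), l1(n, 0.0), l2(n, 0.0), z(n), zo(n), v(n);
  std::vector<double> absd2(n);

  for (int j = 0; j < m; ++j) {
    double ymin = Y(0, j), ymax = Y(0, j);
    for (int i = 0; i < n; ++i) {
      const double yv = Y(i, j);
      if (!R_finite(yv)) stop("non-finite intensity in spectrum %d", j + 1);
      if (yv < ymin) ymin = yv;
      if (yv > ymax) ymax = yv;
    }
    double yrange = ymax - ymin;
    if (yrange <= 0) yrange = 1.0;

    // robust noise scale from second differences: MAD / sqrt(6)
    int n2 = 0;
    for (int i = 0; i + 2 < n; ++i) {
      absd2[n2++] = std::abs(Y(i, j) - 2.0 * Y(i + 1, j) + Y(i + 2, j));
    }
    std::nth_element(absd2.begin(), absd2.begin() + n2 / 2, absd2.begin() + n2);
    const double sigma = 1.4826 * absd2[n2 / 2] / std::sqrt(6.0);
    const double thr = 2.5 * sigma;

    std::fill(w.begin(), w.end(), 1.0);
    std::fill(zo.begin(), zo.end(), 0.0);
    bool done = false;
    int it = 0;
    while (it < maxit && !done) {
      ++it;
      // LDL' factorisation of A = diag(w) + lambda * D2'D2 (bandwidth 2)
      for (int i = 0; i < n; ++i) {
        double di = w[i] + lambda * a0[i];
        if (i >= 1) di -= l1[i - 1] * l1[i - 1] * d[i - 1];
        if (i >= 2) di -= l2[i - 2] * l2[i - 2] * d[i - 2];
        d[i] = di;
        if (i + 2 < n) l2[i] = lambda * a2[i] / di;
        if (i + 1 < n) {
          double s = lambda * a1[i];
          if (i >= 1) s -= l2[i - 1] * d[i - 1] * l1[i - 1];
          l1[i] = s / di;
        }
      }
      // forward solve L v = W y
      for (int i = 0; i < n; ++i) {
        double s = w[i] * Y(i, j);
        if (i >= 1) s -= l1[i - 1] * v[i - 1];
        if (i >= 2) s -= l2[i - 2] * v[i - 2];
        v[i] = s;
      }
      // diagonal + back solve L' z = D^-1 v
      for (int i = n - 1; i >= 0; --i) {
        double s = v[i] / d[i];
        if (i + 1 < n) s -= l1[i] * z[i + 1];
        if (i + 2 < n) s -= l2[i] * z[i + 2];
        z[i] = s;
      }
      // convergence on relative change of the fit
      double dmax = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dv = std::abs(z[i] - zo[i]);
        if (dv > dmax) dmax = dv;
        zo[i] = z[i];
      }
      if (dmax / yrange < tol) {
        done = true;
        break;
      }
      // mask channels above the noise threshold; when a genuine noise
      // scale exists, dilate the mask to cover peak flanks
      std::vector<char> mask(n, 0);
      for (int i = 0; i < n; ++i) mask[i] = (Y(i, j) - z[i] > thr) ? 1 : 0;
      if (sigma > 0 && dilate > 0) {
        std::vector<char> md(n, 0);
        for (int i = 0; i < n; ++i) {
          if (!mask[i]) continue;
          const int lo = std::max(0, i - dilate), hi = std::min(n - 1, i + dilate);
          for (int k = lo; k <= hi; ++k) md[k] = 1;
        }
        mask.swap(md);
      }
      // converged when the mask is (nearly) stable: a handful of channels
      // flickering at the threshold does not move the fit materially
      int nchanged = 0;
      for (int i = 0; i < n; ++i) {
        const double wn = mask[i] ? p : 1.0;
        if (wn != w[i]) ++nchanged;
        w[i] = wn;
      }
      if (nchanged <= n / 200) { done = true; break; }
    }
    iters[j] = it;
    conv[j] = done;
    for (int i = 0; i < n; ++i) Z(i, j) = z[i];
  }

  return List::create(_["baseline"] = Z, _["iterations"] = iters,
                      _["converged"] = conv);
}

// Weighted Whittaker smooth with a FIXED channel mask: masked channels get
// weight p, all others weight 1; a single banded solve per spectrum (no
// reweighting).  Used for the second, class-independent baseline pass of
// differential-band discovery.
// [[Rcpp::export(name = ".whittaker_masked_cpp")]]
NumericMatrix whittaker_masked_cpp(NumericMatrix Y, double lambda, double p,
                                   LogicalVector mask) {
  const int n = Y.nrow(), m = Y.ncol();
  if (n < 4) stop("spectra must have at least 4 channels");
  if (mask.size() != n) stop("mask length must equal channel count");
  if (lambda <= 0) stop("lambda must be positive");
  if (p <= 0 || p > 1) stop("p must be in (0, 1]");

  NumericMatrix Z(n, m);
  std::vector<double> a0(n, 0.0), a1(n, 0.0), a2(n, 0.0);
  const double c[3] = {1.0, -2.0, 1.0};
  for (int r = 0; r + 2 < n; ++r) {
    for (int i = 0; i < 3; ++i) {
      a0[r + i] += c[i] * c[i];
      if (i + 1 < 3) a1[r + i] += c[i] * c[i + 1];
      if (i + 2 < 3) a2[r + i] += c[i] * c[i + 2];
    }
  }
  std::vector<double> w(n), d(n), l1(n, 0.0), l2(n, 0.0), z(n), v(n);
  for (int i = 0; i < n; ++i) w[i] = mask[i] ? p : 1.0;
  // factorisation is shared by all spectra (weights fixed)
  for (int i = 0; i < n; ++i) {
    double di = w[i] + lambda * a0[i];
    if (i >= 1) di -= l1[i - 1] * l1[i - 1] * d[i - 1];
    if (i >= 2) di -= l2[i - 2] * l2[i - 2] * d[i - 2];
    d[i] = di;
    if (i + 2 < n) l2[i] = lambda * a2[i] / di;
    if (i + 1 < n) {
      double s = lambda * a1[i];
      if (i >= 1) s -= l2[i - 1] * d[i - 1] * l1[i - 1];
      l1[i] = s / di;
    }
  }
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (!R_finite(Y(i, j))) stop("non-finite intensity in spectrum %d", j + 1);
      double s = w[i] * Y(i, j);
      if (i >= 1) s -= l1[i - 1] * v[i - 1];
      if (i >= 2) s -= l2[i - 2] * v[i - 2];
      v[i] = s;
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = v[i] / d[i];
      if (i + 1 < n) s -= l1[i] * z[i + 1];
      if (i + 2 < n) s -= l2[i] * z[i + 2];
      z[i] = s;
    }
    for (int i = 0; i < n; ++i) Z(i, j) = z[i];
  }
  return Z;
}
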