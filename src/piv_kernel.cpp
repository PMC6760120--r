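#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct spatial cross-correlation PIV kernel.
//
// For each interrogation node, equal-size windows from the two frames are
// mean-subtracted and correlated directly over integer shifts within
// +/- `margin`, with each lag normalized by its overlap area (unbiased
// estimate) and by the window energies (approximate NCC). Equal windows make
// the autocorrelation plane exactly symmetric, so identical frames yield
// identically zero displacement and swapping frame order negates the
// estimate exactly. The primary peak gets a 3-point subpixel fit per axis;
// the peak ratio is primary/secondary with a 3x3 exclusion zone.
//
// Displacements on the search-range boundary, degenerate (flat) windows and
// windows whose masked fraction exceeds `mask_frac` are flagged invalid.
//
// subpixel: 0 = 3-point Gaussian with parabolic fallback, 1 = parabolic.
// [[Rcpp::export]]
List piv_correlate_cpp(NumericMatrix a, NumericMatrix b,
                       int win, int step, int margin,
                       double min_peak_ratio, int subpixel,
                       LogicalMatrix mask, bool use_mask, double mask_frac) {
  const int nr = a.nrow(), nc = a.ncol();
  const int nwx = (nc - win) / step + 1;
  const int nwy = (nr - win) / step + 1;
  const int side = 2 * margin + 1;

  NumericMatrix dx(nwy, nwx), dy(nwy, nwx), pr(nwy, nwx);
  LogicalMatrix valid(nwy, nwx), masked(nwy, nwx);
  std::vector<double> C(side * side);
  std::vector<double> A(win * win);
  std::vector<double> B(win * win);

  for (int wy = 0; wy < nwy; ++wy) {
    for (int wx = 0; wx < nwx; ++wx) {
      const int r0 = wy * step, c0 = wx * step;
      dx(wy, wx) = NA_REAL; dy(wy, wx) = NA_REAL; pr(wy, wx) = NA_REAL;
      valid(wy, wx) = false; masked(wy, wx) = false;

      if (use_mask) {
        int nm = 0;
        for (int j = 0; j < win; ++j)
          for (int i = 0; i < win; ++i)
            if (mask(r0 + i, c0 + j)) ++nm;
        if (nm > mask_frac * win * win) { masked(wy, wx) = true; continue; }
      }

      // mean-subtracted interrogation window from frame a
      double ma = 0.0;
      for (int j = 0; j < win; ++j)
        for (int i = 0; i < win; ++i) ma += a(r0 + i, c0 + j);
      ma /= (double)(win * win);
      double ea = 0.0;
      for (int j = 0; j < win; ++j)
        for (int i = 0; i < win; ++i) {
          double v = a(r0 + i, c0 + j) - ma;
          A[j * win + i] = v;
          ea += v * v;
        }
      if (ea <= 1e-12) continue;  // flat window: degenerate correlation

      // matching window from frame b, mean-subtracted
      double mb = 0.0;
      for (int j = 0; j < win; ++j)
        for (int i = 0; i < win; ++i) mb += b(r0 + i, c0 + j);
      mb /= (double)(win * win);
      double eb = 0.0;
      for (int j = 0; j < win; ++j) {
        const double* pb = &b(r0, c0 + j);
        double* pB = &B[j * win];
        for (int i = 0; i < win; ++i) {
          const double v = pb[i] - mb;
          pB[i] = v;
          eb += v * v;
        }
      }
      if (eb <= 1e-12) continue;
      const double norm = std::sqrt(ea * eb) / (double)(win * win);

      // correlation plane over the search range, each lag normalized by its
      // overlap area so the estimate is unbiased across lags
      for (int sx = -margin; sx <= margin; ++sx) {
        const int jlo = std::max(0, -sx), jhi = std::min(win, win - sx);
        for (int sy = -margin; sy <= margin; ++sy) {
          const int ilo = std::max(0, -sy), ihi = std::min(win, win - sy);
          double s = 0.0;
          for (int j = jlo; j < jhi; ++j) {
            const double* pa = &A[j * win + ilo];
            const double* pB = &B[(j + sx) * win + (ilo + sy)];
            const int n_i = ihi - ilo;
            for (int i = 0; i < n_i; ++i) s += pa[i] * pB[i];
          }
          const double n_ov = (double)((jhi - jlo) * (ihi - ilo));
          C[(sx + margin) * side + (sy + margin)] = s / (n_ov * norm);
        }
      }

      // primary peak
      int pi = 0, pj = 0; double c1 = C[0];
      for (int j = 0; j < side; ++j)
        for (int i = 0; i < side; ++i)
          if (C[j * side + i] > c1) { c1 = C[j * side + i]; pi = i; pj = j; }
      if (pi == 0 || pi == side - 1 || pj == 0 || pj == side - 1) continue;

      // secondary peak outside the 3x3 neighborhood of the primary
      double c2 = -1e300;
      for (int j = 0; j < side; ++j)
        for (int i = 0; i < side; ++i) {
          if (std::abs(i - pi) <= 1 && std::abs(j - pj) <= 1) continue;
          if (C[j * side + i] > c2) c2 = C[j * side + i];
        }
      const double eps = 1e-6;
      double ratio = (c1 + eps) / (std::max(c2, 0.0) + eps);

      // 3-point subpixel fit per axis
      double cm, cp, dsub[2];
      for (int ax = 0; ax < 2; ++ax) {
        if (ax == 0) { cm = C[pj * side + (pi - 1)]; cp = C[pj * side + (pi + 1)]; }
        else         { cm = C[(pj - 1) * side + pi]; cp = C[(pj + 1) * side + pi]; }
        double d = 0.0;
        if (subpixel == 0 && cm > 0 && cp > 0 && c1 > 0) {
          const double lm = std::log(cm), lp = std::log(cp), l0 = std::log(c1);
          const double den = lm + lp - 2.0 * l0;
          if (den < -1e-300) d = 0.5 * (lm - lp) / den;
        } else {
          const double den = cm + cp - 2.0 * c1;
          if (den < -1e-300) d = 0.5 * (cm - cp) / den;
        }
        if (d > 0.999) d = 0.999; if (d < -0.999) d = -0.999;
        dsub[ax] = d;
      }

      dy(wy, wx) = (pi - margin) + dsub[0];
      dx(wy, wx) = (pj - margin) + dsub[1];
      pr(wy, wx) = ratio;
      valid(wy, wx) = (ratio >= min_peak_ratio);
      if (!valid(wy, wx)) { dx(wy, wx) = NA_REAL; dy(wy, wx) = NA_REAL; }
    }
  }

  return List::create(_["dx"] = dx, _["dy"] = dy, _["peak_ratio"] = pr,
                      _["valid"] = valid, _["masked"] = masked);
}

// Separable Gaussian blur with reflective boundaries (kernel radius 3*sigma).
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> k(2 * rad + 1);
  double ks = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    ks += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= ks;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (dim 1)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        s += k[t + rad] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  // along columns (dim 2)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        s += k[t + rad] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}
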