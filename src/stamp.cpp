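#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Additively stamp pixel-integrated Gaussian spots onto an nr x nc image.
// Coordinates are in pixel units with pixel (i, j) spanning
// [j-1, j] x [i-1, i]; amplitudes are normalized so a spot centered on a
// pixel center contributes `amp` to that pixel.
// [[Rcpp::export]]
NumericMatrix stamp_blobs_cpp(int nr, int nc,
                              NumericVector x, NumericVector y,
                              NumericVector sigma, NumericVector amp) {
  NumericMatrix img(nr, nc);
  const double inv_sqrt2 = 0.7071067811865475;
  std::vector<double> wx(64), wy(64);
  for (int k = 0; k < x.size(); ++k) {
    const double s = sigma[k];
    const double wmax = std::erf(0.5 / s * inv_sqrt2);
    const int rad = (int)std::ceil(4.0 * s) + 1;
    const int j0 = std::max(1, (int)std::floor(x[k] - rad));
    const int j1 = std::min(nc, (int)std::ceil(x[k] + rad));
    const int i0 = std::max(1, (int)std::floor(y[k] - rad));
    const int i1 = std::min(nr, (int)std::ceil(y[k] + rad));
    if (j0 > j1 || i0 > i1) continue;
    const int nx = j1 - j0 + 1, ny = i1 - i0 + 1;
    if ((int)wx.size() < nx) wx.resize(nx);
    if ((int)wy.size() < ny) wy.resize(ny);
    for (int j = 0; j < nx; ++j)
      wx[j] = 0.5 * (std::erf((j0 + j - x[k]) / s * inv_sqrt2) -
                     std::erf((j0 + j - 1 - x[k]) / s * inv_sqrt2));
    for (int i = 0; i < ny; ++i)
      wy[i] = 0.5 * (std::erf((i0 + i - y[k]) / s * inv_sqrt2) -
                     std::erf((i0 + i - 1 - y[k]) / s * inv_sqrt2));
    const double scale = amp[k] / (wmax * wmax);
    for (int j = 0; j < nx; ++j) {
      double* col = &img(i0 - 1, j0 - 1 + j);
      const double aw = scale * wx[j];
      for (int i = 0; i < ny; ++i) col[i] += aw * wy[i];
    }
  }
  return img;
}
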