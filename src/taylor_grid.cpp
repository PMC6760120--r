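#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cholesky solve for a small symmetric positive-definite system G x = r.
// Returns false when G is numerically rank deficient or badly conditioned:
// each pivot must retain at least `rel_tol` of its original diagonal, which
// rejects degenerate sample geometries (collinear or strongly one-sided
// neighborhoods) whose fits extrapolate wildly.
static bool chol_solve(double* G, double* r, int p, double rel_tol) {
  std::vector<double> diag(p);
  for (int j = 0; j < p; ++j) diag[j] = G[j * p + j];
  // in-place lower Cholesky
  for (int j = 0; j < p; ++j) {
    double d = G[j * p + j];
    for (int k = 0; k < j; ++k) d -= G[j * p + k] * G[j * p + k];
    if (d <= rel_tol * diag[j] || d <= 0.0) return false;
    d = std::sqrt(d);
    G[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = G[i * p + j];
      for (int k = 0; k < j; ++k) s -= G[i * p + k] * G[j * p + k];
      G[i * p + j] = s / d;
    }
  }
  for (int i = 0; i < p; ++i) {          // forward
    double s = r[i];
    for (int k = 0; k < i; ++k) s -= G[i * p + k] * r[k];
    r[i] = s / G[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {     // back
    double s = r[i];
    for (int k = i + 1; k < p; ++k) s -= G[k * p + i] * r[k];
    r[i] = s / G[i * p + i];
  }
  return true;
}

// Local weighted-least-squares Taylor-expansion gridding.
//
// At each node all vectors within `radius` are fit, with Gaussian distance
// weights of scale `sigma_w`, to a Taylor polynomial of order 1 or 2 in the
// offsets from the node; the node value is the constant term. Offsets are
// scaled by `radius` for conditioning. Nodes with fewer than `min_count`
// samples, or with rank-deficient normal equations, are flagged invalid.
//
// Returns per-node u, v, sample count, weighted RMS fit residual, validity,
// and a count of rank-deficient nodes.
// [[Rcpp::export]]
List taylor_grid_cpp(NumericVector x, NumericVector y,
                     NumericVector u, NumericVector v,
                     NumericVector node_x, NumericVector node_y,
                     double radius, int order, double sigma_w, int min_count) {
  const int m = x.size(), nx = node_x.size(), ny = node_y.size();
  const int p = (order == 1) ? 3 : 6;
  const double r2 = radius * radius;

  // bin vectors into cells of side `radius`
  double x0 = R_PosInf, y0 = R_PosInf, x1 = R_NegInf, y1 = R_NegInf;
  for (int i = 0; i < m; ++i) {
    if (x[i] < x0) x0 = x[i]; if (x[i] > x1) x1 = x[i];
    if (y[i] < y0) y0 = y[i]; if (y[i] > y1) y1 = y[i];
  }
  const int ncx = std::max(1, (int)std::floor((x1 - x0) / radius) + 1);
  const int ncy = std::max(1, (int)std::floor((y1 - y0) / radius) + 1);
  std::vector< std::vector<int> > cells((size_t)ncx * ncy);
  for (int i = 0; i < m; ++i) {
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor((x[i] - x0) / radius)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor((y[i] - y0) / radius)));
    cells[(size_t)cx * ncy + cy].push_back(i);
  }

  NumericMatrix U(ny, nx), V(ny, nx), RES(ny, nx);
  IntegerMatrix N(ny, nx);
  LogicalMatrix VAL(ny, nx);
  int n_rank_deficient = 0;

  std::vector<int> idx;
  double G[36], Gv[36], ru[6], rv[6], phi[6];

  for (int jx = 0; jx < nx; ++jx) {
    for (int jy = 0; jy < ny; ++jy) {
      const double nxp = node_x[jx], nyp = node_y[jy];
      U(jy, jx) = NA_REAL; V(jy, jx) = NA_REAL; RES(jy, jx) = NA_REAL;
      VAL(jy, jx) = false;

      idx.clear();
      const int cx0 = std::max(0, (int)std::floor((nxp - radius - x0) / radius));
      const int cx1 = std::min(ncx - 1, (int)std::floor((nxp + radius - x0) / radius));
      const int cy0 = std::max(0, (int)std::floor((nyp - radius - y0) / radius));
      const int cy1 = std::min(ncy - 1, (int)std::floor((nyp + radius - y0) / radius));
      for (int cx = cx0; cx <= cx1; ++cx)
        for (int cy = cy0; cy <= cy1; ++cy) {
          const std::vector<int>& cell = cells[(size_t)cx * ncy + cy];
          for (size_t k = 0; k < cell.size(); ++k) {
            const int i = cell[k];
            const double ddx = x[i] - nxp, ddy = y[i] - nyp;
            if (ddx * ddx + ddy * ddy <= r2) idx.push_back(i);
          }
        }
      N(jy, jx) = (int)idx.size();
      if ((int)idx.size() < min_count) continue;

      // support guard: samples must surround the node (at least 3 of the 4
      // quadrants occupied), otherwise the fit extrapolates and amplifies
      // noise (frame edges, mask rims)
      {
        bool q[4] = {false, false, false, false};
        for (size_t k = 0; k < idx.size(); ++k) {
          const double ddx = x[idx[k]] - nxp, ddy = y[idx[k]] - nyp;
          q[(ddx >= 0.0 ? 1 : 0) + (ddy >= 0.0 ? 2 : 0)] = true;
        }
        if ((int)q[0] + (int)q[1] + (int)q[2] + (int)q[3] < 3) continue;
      }

      const size_t m_loc = idx.size();
      std::vector<char> use(m_loc, 1);
      std::vector<double> Xl(m_loc), Yl(m_loc), Wl(m_loc), res_k(m_loc);
      for (size_t k = 0; k < m_loc; ++k) {
        Xl[k] = (x[idx[k]] - nxp) / radius;
        Yl[k] = (y[idx[k]] - nyp) / radius;
        Wl[k] = std::exp(-0.5 * (Xl[k] * Xl[k] + Yl[k] * Yl[k]) * r2 /
                         (sigma_w * sigma_w));
      }

      const double cond_tol = 0.02;   // relative pivot floor (geometry check)
      bool ok = false;
      double wrms = 0.0;
      // one robust refit pass: samples whose residual exceeds 3x the
      // weighted RMS (spurious matches) are discarded and the node refit
      for (int pass = 0; pass < 2; ++pass) {
        for (int i = 0; i < p * p; ++i) G[i] = 0.0;
        for (int i = 0; i < p; ++i) { ru[i] = 0.0; rv[i] = 0.0; }
        int nuse = 0;
        for (size_t k = 0; k < m_loc; ++k) {
          if (!use[k]) continue;
          ++nuse;
          const double w = Wl[k];
          phi[0] = 1.0; phi[1] = Xl[k]; phi[2] = Yl[k];
          if (p == 6) {
            phi[3] = Xl[k] * Xl[k]; phi[4] = Xl[k] * Yl[k];
            phi[5] = Yl[k] * Yl[k];
          }
          const int i = idx[k];
          for (int ai = 0; ai < p; ++ai) {
            const double wf = w * phi[ai];
            for (int aj = 0; aj <= ai; ++aj) G[ai * p + aj] += wf * phi[aj];
            ru[ai] += wf * u[i];
            rv[ai] += wf * v[i];
          }
        }
        if (nuse < min_count) { ok = false; break; }
        for (int ai = 0; ai < p; ++ai)
          for (int aj = ai + 1; aj < p; ++aj) G[ai * p + aj] = G[aj * p + ai];
        for (int i = 0; i < p * p; ++i) Gv[i] = G[i];
        ok = chol_solve(G, ru, p, cond_tol) && chol_solve(Gv, rv, p, cond_tol);
        if (!ok) break;

        double sw = 0.0, sr = 0.0;
        for (size_t k = 0; k < m_loc; ++k) {
          if (!use[k]) { res_k[k] = 0.0; continue; }
          double fu = ru[0] + ru[1] * Xl[k] + ru[2] * Yl[k];
          double fv = rv[0] + rv[1] * Xl[k] + rv[2] * Yl[k];
          if (p == 6) {
            fu += ru[3] * Xl[k] * Xl[k] + ru[4] * Xl[k] * Yl[k] +
                  ru[5] * Yl[k] * Yl[k];
            fv += rv[3] * Xl[k] * Xl[k] + rv[4] * Xl[k] * Yl[k] +
                  rv[5] * Yl[k] * Yl[k];
          }
          const int i = idx[k];
          const double du = u[i] - fu, dv = v[i] - fv;
          res_k[k] = std::sqrt(du * du + dv * dv);
          sr += Wl[k] * (du * du + dv * dv);
          sw += 2.0 * Wl[k];
        }
        wrms = std::sqrt(sr / sw);
        if (pass == 1) break;
        int ndrop = 0;
        if (wrms > 1e-300)
          for (size_t k = 0; k < m_loc; ++k)
            if (use[k] && res_k[k] > 3.0 * wrms * 1.4142135623730951) {
              use[k] = 0; ++ndrop;
            }
        if (ndrop == 0) break;
      }
      if (!ok) { ++n_rank_deficient; continue; }

      U(jy, jx) = ru[0];
      V(jy, jx) = rv[0];
      RES(jy, jx) = wrms;
      VAL(jy, jx) = true;
    }
  }

  return List::create(_["u"] = U, _["v"] = V, _["n"] = N, _["residual"] = RES,
                      _["valid"] = VAL, _["n_rank_deficient"] = n_rank_deficient);
}
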