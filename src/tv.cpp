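// Chambolle dual projection iteration for the 3D ROF model
//   min_u 0.5*||u - f||^2 + weight * TV(u)
// Forward differences with Neumann boundaries; dual step 1/12 (safe for
// the 3D discrete divergence-gradient operator norm).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector chambolle_tv_cpp(NumericVector f, double weight, int max_iter,
                               double tol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  const double tau = 1.0 / 12.0;

  std::vector<double> p1(n, 0.0), p2(n, 0.0), p3(n, 0.0);
  std::vector<double> divp(n, 0.0), g(n, 0.0);
  NumericVector u(n);

  double fmean = 0.0, fmaxdev = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) fmean += f[i];
  fmean /= n;
  for (R_xlen_t i = 0; i < n; ++i)
    fmaxdev = std::max(fmaxdev, std::fabs(f[i] - fmean));
  const double scale = std::max(fmaxdev, 1e-12);

  for (R_xlen_t i = 0; i < n; ++i) u[i] = f[i];

  auto idx = [&](int x, int y, int z) -> R_xlen_t {
    return x + static_cast<R_xlen_t>(nx) * (y + static_cast<R_xlen_t>(ny) * z);
  };

  auto compute_div = [&]() {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t i = idx(x, y, z);
          double d = 0.0;
          // backward-difference divergence, adjoint of the forward gradient
          if (nx > 1) {
            if (x == 0) d += p1[i];
            else if (x == nx - 1) d += -p1[idx(x - 1, y, z)];
            else d += p1[i] - p1[idx(x - 1, y, z)];
          }
          if (ny > 1) {
            if (y == 0) d += p2[i];
            else if (y == ny - 1) d += -p2[idx(x, y - 1, z)];
            else d += p2[i] - p2[idx(x, y - 1, z)];
          }
          if (nz > 1) {
            if (z == 0) d += p3[i];
            else if (z == nz - 1) d += -p3[idx(x, y, z - 1)];
            else d += p3[i] - p3[idx(x, y, z - 1)];
          }
          divp[i] = d;
        }
      }
    }
  };

  for (int it = 0; it < max_iter; ++it) {
    compute_div();
    for (R_xlen_t i = 0; i < n; ++i) g[i] = divp[i] - f[i] / weight;
    double delta = 0.0;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t i = idx(x, y, z);
          const double g1 = (x < nx - 1) ? g[idx(x + 1, y, z)] - g[i] : 0.0;
          const double g2 = (y < ny - 1) ? g[idx(x, y + 1, z)] - g[i] : 0.0;
          const double g3 = (z < nz - 1) ? g[idx(x, y, z + 1)] - g[i] : 0.0;
          const double denom =
              1.0 + tau * std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
          p1[i] = (p1[i] + tau * g1) / denom;
          p2[i] = (p2[i] + tau * g2) / denom;
          p3[i] = (p3[i] + tau * g3) / denom;
        }
      }
    }
    compute_div();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double u_new = f[i] - weight * divp[i];
      delta = std::max(delta, std::fabs(u_new - u[i]));
      u[i] = u_new;
    }
    if (delta / scale < tol) break;
  }
  return u;
}
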