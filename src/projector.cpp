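#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a 2D grid at physical point (x, y).
// Grid value g(i, j) sits at x = ox + i*sp, y = oy + j*sp (0-based).
// Points outside the grid contribute 0.
static inline double bilinear(const double* g, int nx, int ny,
                              double ox, double oy, double sp,
                              double x, double y) {
  double gx = (x - ox) / sp;
  double gy = (y - oy) / sp;
  if (gx < 0.0 || gy < 0.0 || gx > nx - 1.0 || gy > ny - 1.0) return 0.0;
  int i0 = (int)gx, j0 = (int)gy;
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  double fx = gx - i0, fy = gy - j0;
  const double* c = g + (size_t)j0 * nx + i0;
  double v00 = c[0], v10 = c[1], v01 = c[nx], v11 = c[nx + 1];
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Fan-beam line integrals for a flat detector.
// mu: nx x ny attenuation grid (mm^-1), column j = y index (R column-major
//     matrix with nx rows is passed as-is: element (i, j) = mu[j*nx + i]).
// beta: source angles, radians, math convention (source at sad*(cos b, sin b)).
// udet: detector coordinates (mm, at the detector plane, sdd from source).
// step: ray sampling step (mm).
// Returns ndet x nangle matrix of integral(mu dl) (dimensionless).
// [[Rcpp::export]]
NumericMatrix cpp_fan_forward(NumericMatrix mu, double spacing,
                              double ox, double oy,
                              NumericVector beta, double sad, double sdd,
                              NumericVector udet, double step) {
  const int nx = mu.nrow(), ny = mu.ncol();
  const int nb = beta.size(), nu = udet.size();
  const double* g = mu.begin();
  // bounding radius of the grid around the isocenter
  double rx = std::max(std::fabs(ox), std::fabs(ox + (nx - 1) * spacing));
  double ry = std::max(std::fabs(oy), std::fabs(oy + (ny - 1) * spacing));
  double rb = std::sqrt(rx * rx + ry * ry) + spacing;
  int ns = (int)std::ceil(2.0 * rb / step) + 1;
  NumericMatrix out(nu, nb);
  for (int k = 0; k < nb; ++k) {
    double cb = std::cos(beta[k]), sb = std::sin(beta[k]);
    double sx = sad * cb, sy = sad * sb;          // source
    double ecx = -cb, ecy = -sb;                  // toward isocenter
    double epx = -sb, epy = cb;                   // detector axis
    for (int i = 0; i < nu; ++i) {
      double px = sx + sdd * ecx + udet[i] * epx;
      double py = sy + sdd * ecy + udet[i] * epy;
      double dx = px - sx, dy = py - sy;
      double len = std::sqrt(dx * dx + dy * dy);
      dx /= len; dy /= len;
      double t0 = sad - rb;
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) {
        double t = t0 + s * step;
        acc += bilinear(g, nx, ny, ox, oy, spacing, sx + t * dx, sy + t * dy);
      }
      out(i, k) = acc * step;
    }
  }
  return out;
}

// Weighted fan-beam backprojection onto an nx x ny pixel grid.
// q: ndet x nangle filtered (and redundancy-weighted) projections sampled at
//    isocenter-scaled detector coordinates u0 + i*du.
// wang: per-angle weight (angular step in radians, possibly premultiplied).
// Accumulates wang[k] * (sad/L)^2 * q(u_iso) with linear interpolation in u,
// where L is the pixel's distance from the source along the central ray.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix q, NumericVector beta,
                                  double sad, double u0, double du,
                                  int nx, int ny, double pixel,
                                  double ox, double oy, NumericVector wang) {
  const int nu = q.nrow(), nb = q.ncol();
  NumericMatrix img(nx, ny);
  for (int k = 0; k < nb; ++k) {
    double cb = std::cos(beta[k]), sb = std::sin(beta[k]);
    const double* col = &q(0, k);
    double w = wang[k];
    for (int j = 0; j < ny; ++j) {
      double y = oy + j * pixel;
      for (int i = 0; i < nx; ++i) {
        double x = ox + i * pixel;
        double L = sad - (x * cb + y * sb);       // (X - S) . e_c
        if (L <= 1e-9) continue;
        double up = (-x * sb + y * cb);           // (X - S) . e_p
        double uiso = sad * up / L;
        double fi = (uiso - u0) / du;
        if (fi < 0.0 || fi > nu - 1.0) continue;
        int i0 = (int)fi;
        if (i0 >= nu - 1) i0 = nu - 2;
        double f = fi - i0;
        double val = col[i0] * (1 - f) + col[i0 + 1] * f;
        double mag = sad / L;
        img(i, j) += w * mag * mag * val;
      }
    }
  }
  return img;
}
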