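#include <Rcpp.h>
using namespace Rcpp;

// Gradient vector flow diffusion (Xu & Prince). fx, fy are the components of
// the edge-map gradient; the field (u, v) is initialized at (fx, fy) and
// relaxed under  u_t = mu * laplacian(u) - (fx^2 + fy^2) * (u - fx)
// with replicated (Neumann) boundaries. Matrices are [row, col] = [y, x].
// [[Rcpp::export(name = ".gvf_diffuse")]]
List gvf_diffuse(NumericMatrix fx, NumericMatrix fy, double mu, int iterations) {
  const int nr = fx.nrow(), nc = fx.ncol();
  NumericMatrix u(clone(fx)), v(clone(fy)), un(nr, nc), vn(nr, nc);
  NumericMatrix b(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      b(i, j) = fx(i, j) * fx(i, j) + fy(i, j) * fy(i, j);

  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < nc; ++j) {
      const int jl = j > 0 ? j - 1 : 0, jr = j < nc - 1 ? j + 1 : nc - 1;
      for (int i = 0; i < nr; ++i) {
        const int iu = i > 0 ? i - 1 : 0, id = i < nr - 1 ? i + 1 : nr - 1;
        const double lapU = u(iu, j) + u(id, j) + u(i, jl) + u(i, jr) - 4.0 * u(i, j);
        const double lapV = v(iu, j) + v(id, j) + v(i, jl) + v(i, jr) - 4.0 * v(i, j);
        un(i, j) = u(i, j) + mu * lapU - b(i, j) * (u(i, j) - fx(i, j));
        vn(i, j) = v(i, j) + mu * lapV - b(i, j) * (v(i, j) - fy(i, j));
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
  }
  return List::create(_["u"] = u, _["v"] = v);
}

static inline double bilinear(const NumericMatrix& m, double x, double y) {
  // x indexes columns, y indexes rows; 0-based pixel-center coordinates,
  // clamped to the grid.
  const int nr = m.nrow(), nc = m.ncol();
  if (x < 0) x = 0; if (x > nc - 1) x = nc - 1;
  if (y < 0) y = 0; if (y > nr - 1) y = nr - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = x0 < nc - 1 ? x0 + 1 : x0, y1 = y0 < nr - 1 ? y0 + 1 : y0;
  const double dx = x - x0, dy = y - y0;
  return m(y0, x0) * (1 - dx) * (1 - dy) + m(y0, x1) * dx * (1 - dy) +
         m(y1, x0) * (1 - dx) * dy + m(y1, x1) * dx * dy;
}

// One batch of semi-implicit snake deformations:
//   x <- M (gamma * x + kappa * u(x, y)),  M = (K + gamma I)^{-1}
// where K is the cyclic pentadiagonal internal-energy (tension/rigidity)
// matrix, precomputed and inverted in R. u, v are the external force
// components sampled bilinearly at the current vertices.
// [[Rcpp::export(name = ".snake_deform")]]
List snake_deform(NumericVector x, NumericVector y,
                  const NumericMatrix& u, const NumericMatrix& v,
                  const NumericMatrix& M, double gamma, double kappa,
                  int n_iter) {
  const int n = x.size();
  NumericVector cx(clone(x)), cy(clone(y)), rx(n), ry(n), nx(n), ny(n);
  for (int it = 0; it < n_iter; ++it) {
    for (int k = 0; k < n; ++k) {
      rx[k] = gamma * cx[k] + kappa * bilinear(u, cx[k], cy[k]);
      ry[k] = gamma * cy[k] + kappa * bilinear(v, cx[k], cy[k]);
    }
    for (int i = 0; i < n; ++i) {
      double sx = 0.0, sy = 0.0;
      for (int k = 0; k < n; ++k) {
        sx += M(i, k) * rx[k];
        sy += M(i, k) * ry[k];
      }
      nx[i] = sx;
      ny[i] = sy;
    }
    std::copy(nx.begin(), nx.end(), cx.begin());
    std::copy(ny.begin(), ny.end(), cy.begin());
  }
  return List::create(_["x"] = cx, _["y"] = cy);
}

// Grayscale morphological reconstruction by erosion (hybrid raster
// algorithm, 4-connected): the smallest image >= mask obtainable by
// repeatedly eroding marker and clamping at mask. Used for gray-scale hole
// filling with marker = +range except image values on the border.
// [[Rcpp::export(name = ".reconstruct_erode")]]
NumericMatrix reconstruct_erode(NumericMatrix marker, const NumericMatrix& mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix m(clone(marker));
  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= 4 * (nr + nc)) {
    changed = false;
    // forward raster: take min with already-visited (up, left) neighbours
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double val = m(i, j);
        if (i > 0 && m(i - 1, j) < val) val = m(i - 1, j);
        if (j > 0 && m(i, j - 1) < val) val = m(i, j - 1);
        if (val < mask(i, j)) val = mask(i, j);
        if (val != m(i, j)) { m(i, j) = val; changed = true; }
      }
    // backward raster: (down, right) neighbours
    for (int j = nc - 1; j >= 0; --j)
      for (int i = nr - 1; i >= 0; --i) {
        double val = m(i, j);
        if (i < nr - 1 && m(i + 1, j) < val) val = m(i + 1, j);
        if (j < nc - 1 && m(i, j + 1) < val) val = m(i, j + 1);
        if (val < mask(i, j)) val = mask(i, j);
        if (val != m(i, j)) { m(i, j) = val; changed = true; }
      }
  }
  return m;
}
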