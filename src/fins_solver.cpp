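#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Split Bregman minimisation of the relaxed two-phase segmentation energy
//
//   min_{u in [0,1]}  sum |grad u|  +  lambda * sum f * u
//
// with isotropic TV on a forward-difference discretisation (Neumann /
// replicate boundary). Auxiliary field d ~ grad u with Bregman variable b:
//   u-step : one Gauss-Seidel sweep of  mu*Lap(u) = lambda*f + mu*div(d - b),
//            followed by clipping u into [0,1]
//   d-step : vector shrinkage d = shrink(grad u + b, 1/mu)
//   b-step : b <- b + grad u - d
// Stops when ||u_k+1 - u_k|| / ||u_k|| < tol, or at max_iter.
//
// Matrices are column-major; rows index y, columns index x.

// [[Rcpp::export]]
List sb_segment(NumericMatrix f, NumericMatrix u0, double lambda, double mu,
                double tol, int max_iter) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix u(nr, nc);
  std::copy(u0.begin(), u0.end(), u.begin());

  NumericMatrix dx(nr, nc), dy(nr, nc), bx(nr, nc), by(nr, nc);
  std::vector<double> uold(static_cast<size_t>(nr) * nc);

  const double lam_mu = lambda / mu;
  const double shrink_t = 1.0 / mu;
  double relchg = R_PosInf;
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    std::copy(u.begin(), u.end(), uold.begin());

    // Gauss-Seidel sweep, in place; replicate boundary via index clamping.
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const int im = i > 0 ? i - 1 : i, ip = i < nr - 1 ? i + 1 : i;
        const int jm = j > 0 ? j - 1 : j, jp = j < nc - 1 ? j + 1 : j;
        // div(d - b) with backward differences (adjoint of forward gradient)
        double div = (dx(i, j) - bx(i, j)) + (dy(i, j) - by(i, j));
        if (j > 0) div -= dx(i, j - 1) - bx(i, j - 1);
        if (i > 0) div -= dy(i - 1, j) - by(i - 1, j);
        double v = (u(i, jm) + u(i, jp) + u(im, j) + u(ip, j) - div -
                    lam_mu * f(i, j)) / 4.0;
        u(i, j) = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
      }
    }

    // Shrinkage of d = grad u + b, then Bregman update b = g - d.
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double gx = (j < nc - 1 ? u(i, j + 1) - u(i, j) : 0.0) + bx(i, j);
        const double gy = (i < nr - 1 ? u(i + 1, j) - u(i, j) : 0.0) + by(i, j);
        const double s = std::sqrt(gx * gx + gy * gy);
        double scale = 0.0;
        if (s > shrink_t) scale = (s - shrink_t) / s;
        dx(i, j) = scale * gx;
        dy(i, j) = scale * gy;
        bx(i, j) = gx - dx(i, j);
        by(i, j) = gy - dy(i, j);
      }
    }

    double num = 0.0, den = 0.0;
    for (size_t k = 0; k < uold.size(); ++k) {
      const double d0 = u[k] - uold[k];
      num += d0 * d0;
      den += uold[k] * uold[k];
    }
    if (den > 0.0) {
      relchg = std::sqrt(num / den);
      if (relchg < tol) { converged = true; break; }
    } else if (num == 0.0) {        // u stayed identically zero
      relchg = 0.0;
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;

  return List::create(_["u"] = u, _["iterations"] = it,
                      _["converged"] = converged, _["rel_change"] = relchg);
}

// Connected-component labelling of a binary mask under 4- or 8-connectivity.
// Components are numbered 1..n in raster-scan order of their first pixel
// (row-major: scan row by row, left to right).

// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;

  const int n4i[4] = {-1, 1, 0, 0}, n4j[4] = {0, 0, -1, 1};
  const int n8i[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
            n8j[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  const int *di = connectivity == 8 ? n8i : n4i;
  const int *dj = connectivity == 8 ? n8j : n4j;

  for (int i = 0; i < nr; ++i) {        // row-major raster order
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          const int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
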