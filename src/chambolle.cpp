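#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Chambolle dual projection for the ROF structure-texture split:
//   u = argmin TV(u) + ||u - g||^2 / (2*mu),
// iterated as p <- (p + tau * grad(div p - g/mu)) / (1 + tau * |...|),
// u = g - mu * div p.  Forward differences with Neumann boundary, the
// adjoint divergence (texture is exactly zero-mean by telescoping).
//
// Stopping: the iteration halts once the structure increment
// ||u_k - u_{k-1}|| falls below `tol` times the first increment
// (relative decay), or at max_iters.  Returns the structure and the
// number of projections NI actually used.

// [[Rcpp::export]]
List cpp_chambolle(NumericMatrix image, double mu, double tau,
                   int max_iters, double tol) {
  const int nr = image.nrow(), nc = image.ncol();
  NumericMatrix p1(nr, nc), p2(nr, nc), u(nr, nc), divp(nr, nc);
  std::vector<double> uprev(nr * nc);
  for (int i = 0; i < nr * nc; ++i) {
    u[i] = image[i];
    uprev[i] = image[i];
  }
  double inc1 = -1.0;
  int ni = max_iters;

  for (int k = 1; k <= max_iters; ++k) {
    // div p (adjoint of forward differences)
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double dx, dy;
        if (c == 0) dx = p1(r, 0);
        else if (c == nc - 1) dx = -p1(r, nc - 2);
        else dx = p1(r, c) - p1(r, c - 1);
        if (r == 0) dy = p2(0, c);
        else if (r == nr - 1) dy = -p2(nr - 2, c);
        else dy = p2(r, c) - p2(r - 1, c);
        divp(r, c) = dx + dy;
      }
    }
    // dual update from grad(div p - g/mu)
    bool bad = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const double w0 = divp(r, c) - image(r, c) / mu;
        const double gx = (c < nc - 1)
          ? (divp(r, c + 1) - image(r, c + 1) / mu) - w0 : 0.0;
        const double gy = (r < nr - 1)
          ? (divp(r + 1, c) - image(r + 1, c) / mu) - w0 : 0.0;
        const double den = 1.0 + tau * std::sqrt(gx * gx + gy * gy);
        p1(r, c) = (p1(r, c) + tau * gx) / den;
        p2(r, c) = (p2(r, c) + tau * gy) / den;
        if (!std::isfinite(p1(r, c)) || !std::isfinite(p2(r, c))) bad = true;
      }
    }
    if (bad) stop("dual projection diverged (non-finite) at iteration %d", k);
    // u = g - mu * div p ; increment norm
    double inc = 0.0;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double dx, dy;
        if (c == 0) dx = p1(r, 0);
        else if (c == nc - 1) dx = -p1(r, nc - 2);
        else dx = p1(r, c) - p1(r, c - 1);
        if (r == 0) dy = p2(0, c);
        else if (r == nr - 1) dy = -p2(nr - 2, c);
        else dy = p2(r, c) - p2(r - 1, c);
        const double val = image(r, c) - mu * (dx + dy);
        const double d = val - uprev[c * nr + r];
        inc += d * d;
        u(r, c) = val;
        uprev[c * nr + r] = val;
      }
    }
    inc = std::sqrt(inc);
    if (inc1 < 0.0) inc1 = (inc > 0.0) ? inc : -2.0;
    if (inc1 == -2.0 || (inc1 > 0.0 && inc / inc1 < tol)) {
      ni = k;
      break;
    }
  }
  return List::create(_["structure"] = u, _["NI"] = ni);
}
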