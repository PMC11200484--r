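#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Replicated-edge (Neumann) index clamp.
static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Central-difference gradients, replicated edges.  x runs along columns,
// y along rows, unit pixel spacing.
// [[Rcpp::export]]
List cpp_grad(NumericMatrix f) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
      gx(i, j) = 0.5 * (f(i, jp) - f(i, jm));
      gy(i, j) = 0.5 * (f(ip, j) - f(im, j));
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Divergence of a vector field (fx, fy) by central differences.
// [[Rcpp::export]]
NumericMatrix cpp_divergence(NumericMatrix fx, NumericMatrix fy) {
  const int nr = fx.nrow(), nc = fx.ncol();
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
      d(i, j) = 0.5 * (fx(i, jp) - fx(i, jm)) + 0.5 * (fy(ip, j) - fy(im, j));
    }
  }
  return d;
}

// Mean curvature kappa = div(grad phi / |grad phi|) with the gradient
// magnitude floored to avoid division blow-up.
// [[Rcpp::export]]
NumericMatrix cpp_curvature(NumericMatrix phi, double grad_floor) {
  const int nr = phi.nrow(), nc = phi.ncol();
  NumericMatrix nx(nr, nc), ny(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
      const double gx = 0.5 * (phi(i, jp) - phi(i, jm));
      const double gy = 0.5 * (phi(ip, j) - phi(im, j));
      double nrm = std::sqrt(gx * gx + gy * gy);
      if (nrm < grad_floor) nrm = grad_floor;
      nx(i, j) = gx / nrm;
      ny(i, j) = gy / nrm;
    }
  }
  return cpp_divergence(nx, ny);
}

// Separable Gaussian blur, kernel truncated at 4 sigma, replicated edges.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * (double)(t * t) / (sigma * sigma));
    ksum += k[t + rad];
  }
  for (size_t t = 0; t < k.size(); ++t) k[t] /= ksum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // horizontal pass (along columns = x)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) acc += k[t + rad] * img(i, clampi(j + t, nc));
      tmp(i, j) = acc;
    }
  // vertical pass
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) acc += k[t + rad] * tmp(clampi(i + t, nr), j);
      out(i, j) = acc;
    }
  return out;
}

// Canny non-maximum suppression: keep gradient-magnitude ridge pixels,
// directions quantized to 4 sectors.
// [[Rcpp::export]]
NumericMatrix cpp_canny_nms(NumericMatrix mag, NumericMatrix gx, NumericMatrix gy) {
  const int nr = mag.nrow(), nc = mag.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double m = mag(i, j);
      if (m <= 0) { out(i, j) = 0; continue; }
      const double ang = std::atan2(gy(i, j), gx(i, j));
      // sector of the gradient direction: 0 = E/W, 1 = NE/SW, 2 = N/S, 3 = NW/SE
      int sec = (int)std::lround(ang / (M_PI / 4.0));
      sec = ((sec % 4) + 4) % 4;
      int di = 0, dj = 0;
      switch (sec) {
        case 0: di = 0; dj = 1; break;
        case 1: di = 1; dj = 1; break;
        case 2: di = 1; dj = 0; break;
        default: di = 1; dj = -1; break;
      }
      const double m1 = mag(clampi(i + di, nr), clampi(j + dj, nc));
      const double m2 = mag(clampi(i - di, nr), clampi(j - dj, nc));
      out(i, j) = (m >= m1 && m >= m2) ? m : 0.0;
    }
  return out;
}

// Hysteresis thresholding: BFS from strong pixels through weak pixels,
// 8-connected.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(NumericMatrix mag, double lo, double hi) {
  const int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mag(i, j) >= hi && !out(i, j)) {
        out(i, j) = true;
        stack.push_back(std::make_pair(i, j));
      }
  while (!stack.empty()) {
    const std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        const int ii = p.first + di, jj = p.second + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!out(ii, jj) && mag(ii, jj) >= lo) {
          out(ii, jj) = true;
          stack.push_back(std::make_pair(ii, jj));
        }
      }
  }
  return out;
}

// Fill interior holes of a binary mask: flood the background from the image
// border (4-connected); anything not reached and not mask is a hole.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reached(nr, nc);
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    if (!mask(0, j) && !reached(0, j)) { reached(0, j) = true; stack.push_back(std::make_pair(0, j)); }
    if (!mask(nr - 1, j) && !reached(nr - 1, j)) { reached(nr - 1, j) = true; stack.push_back(std::make_pair(nr - 1, j)); }
  }
  for (int i = 0; i < nr; ++i) {
    if (!mask(i, 0) && !reached(i, 0)) { reached(i, 0) = true; stack.push_back(std::make_pair(i, 0)); }
    if (!mask(i, nc - 1) && !reached(i, nc - 1)) { reached(i, nc - 1) = true; stack.push_back(std::make_pair(i, nc - 1)); }
  }
  const int di[4] = { -1, 1, 0, 0 };
  const int dj[4] = { 0, 0, -1, 1 };
  while (!stack.empty()) {
    const std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int t = 0; t < 4; ++t) {
      const int ii = p.first + di[t], jj = p.second + dj[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) && !reached(ii, jj)) {
        reached(ii, jj) = true;
        stack.push_back(std::make_pair(ii, jj));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reached(i, j);
  return out;
}

static inline double dirac_eps(double x, double eps) {
  if (std::fabs(x) > eps) return 0.0;
  return (1.0 + std::cos(M_PI * x / eps)) / (2.0 * eps);
}

static inline double heaviside_eps(double x, double eps) {
  if (x > eps) return 1.0;
  if (x < -eps) return 0.0;
  return 0.5 * (1.0 + x / eps + std::sin(M_PI * x / eps) / M_PI);
}

// Smoothed-indicator region means; returns c(c1_inside, c2_outside,
// w_inside, w_outside).  Inside-negative convention.
// [[Rcpp::export]]
NumericVector cpp_region_means(NumericMatrix I, NumericMatrix phi, double eps) {
  const int n = I.size();
  double si = 0, so = 0, wi = 0, wo = 0;
  for (int t = 0; t < n; ++t) {
    const double h = heaviside_eps(phi[t], eps);
    wi += 1.0 - h;
    wo += h;
    si += I[t] * (1.0 - h);
    so += I[t] * h;
  }
  return NumericVector::create(wi > 0 ? si / wi : NA_REAL,
                               wo > 0 ? so / wo : NA_REAL, wi, wo);
}

// Full right-hand side of the convexity-preserving model:
// delta * (s*(l1(I-c1)^2 - l2(I-c2)^2) + alpha*kappa + mu*g + beta*(1-s)*kappa)
// with s = indicator(blur(kappa, csi_sigma) >= 0).
// [[Rcpp::export]]
NumericMatrix cpp_proposed_step(NumericMatrix phi, NumericMatrix I,
                                NumericMatrix g, double c1, double c2,
                                double lambda1, double lambda2, double alpha,
                                double mu, double beta, double eps,
                                double csi_sigma) {
  NumericMatrix kappa = cpp_curvature(phi, 1e-8);
  NumericMatrix ks = csi_sigma > 0 ? cpp_gauss_blur(kappa, csi_sigma) : kappa;
  const int n = phi.size();
  NumericMatrix out(phi.nrow(), phi.ncol());
  for (int t = 0; t < n; ++t) {
    const double d = dirac_eps(phi[t], eps);
    if (d == 0.0) { out[t] = 0.0; continue; }
    const double s = ks[t] >= 0 ? 1.0 : 0.0;
    const double r1 = I[t] - c1, r2 = I[t] - c2;
    const double data = lambda1 * r1 * r1 - lambda2 * r2 * r2;
    out[t] = d * (s * data + alpha * kappa[t] + mu * g[t] +
                  beta * (1.0 - s) * kappa[t]);
  }
  return out;
}

// Chan-Vese gradient flow under the inside-negative convention:
// delta * (mu_cv*kappa + v + l1(I-c1)^2 - l2(I-c2)^2), v per-pixel.
// [[Rcpp::export]]
NumericMatrix cpp_cv_step(NumericMatrix phi, NumericMatrix I, NumericMatrix v,
                          double c1, double c2, double lambda1,
                          double lambda2, double mu_cv, double eps) {
  NumericMatrix kappa = cpp_curvature(phi, 1e-8);
  const int n = phi.size();
  NumericMatrix out(phi.nrow(), phi.ncol());
  for (int t = 0; t < n; ++t) {
    const double d = dirac_eps(phi[t], eps);
    if (d == 0.0) { out[t] = 0.0; continue; }
    const double r1 = I[t] - c1, r2 = I[t] - c2;
    out[t] = d * (mu_cv * kappa[t] + v[t] + lambda1 * r1 * r1 - lambda2 * r2 * r2);
  }
  return out;
}

// CPLSE right-hand side: mu_reg*div(dp(|grad phi|) grad phi)
//  + s*(lambda_len*delta*div(g n) + alpha_area*g*delta) + (1-s)*kappa*delta.
// [[Rcpp::export]]
NumericMatrix cpp_cplse_step(NumericMatrix phi, NumericMatrix g,
                             double mu_reg, double lambda_len,
                             double alpha_area, double eps,
                             double csi_sigma) {
  const int nr = phi.nrow(), nc = phi.ncol();
  NumericMatrix px(nr, nc), py(nr, nc), nx(nr, nc), ny(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
      const double gx = 0.5 * (phi(i, jp) - phi(i, jm));
      const double gy = 0.5 * (phi(ip, j) - phi(im, j));
      const double nrm = std::sqrt(gx * gx + gy * gy);
      double dp;
      if (nrm < 1.0)
        dp = nrm == 0.0 ? 1.0 : std::sin(2.0 * M_PI * nrm) / (2.0 * M_PI * nrm);
      else
        dp = (nrm - 1.0) / nrm;
      px(i, j) = dp * gx;
      py(i, j) = dp * gy;
      const double nf = nrm < 1e-8 ? 1e-8 : nrm;
      nx(i, j) = g(i, j) * gx / nf;
      ny(i, j) = g(i, j) * gy / nf;
    }
  }
  NumericMatrix reg = cpp_divergence(px, py);
  NumericMatrix len = cpp_divergence(nx, ny);
  NumericMatrix kappa = cpp_curvature(phi, 1e-8);
  NumericMatrix ks = csi_sigma > 0 ? cpp_gauss_blur(kappa, csi_sigma) : kappa;
  NumericMatrix out(nr, nc);
  const int n = phi.size();
  for (int t = 0; t < n; ++t) {
    const double d = dirac_eps(phi[t], eps);
    const double s = ks[t] >= 0 ? 1.0 : 0.0;
    out[t] = mu_reg * reg[t] +
      s * (lambda_len * d * len[t] + alpha_area * g[t] * d) +
      (1.0 - s) * kappa[t] * d;
  }
  return out;
}

// Sign-preserving redistancing: sweeps of
//   phi_tau = S(phi_ref) (1 - |grad phi|_Godunov)
// with the smoothed sign S = phi/sqrt(phi^2+1) taken from the field at
// entry.  Upwind (Godunov) gradients, replicated edges.
// [[Rcpp::export]]
NumericMatrix cpp_redistance(NumericMatrix phi0, int sweeps, double dtau) {
  const int nr = phi0.nrow(), nc = phi0.ncol();
  NumericMatrix phi = clone(phi0), sgn(nr, nc);
  const int n = phi.size();
  for (int t = 0; t < n; ++t) sgn[t] = phi[t] / std::sqrt(phi[t] * phi[t] + 1.0);
  NumericMatrix upd(nr, nc);
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int j = 0; j < nc; ++j) {
      const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
      for (int i = 0; i < nr; ++i) {
        const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
        const double a = phi(i, j) - phi(i, jm);   // backward x
        const double b = phi(i, jp) - phi(i, j);   // forward x
        const double c = phi(i, j) - phi(im, j);   // backward y
        const double d = phi(ip, j) - phi(i, j);   // forward y
        double gm;
        if (sgn(i, j) > 0) {
          const double ap = a > 0 ? a : 0, bm = b < 0 ? b : 0;
          const double cp = c > 0 ? c : 0, dm = d < 0 ? d : 0;
          gm = std::sqrt(std::max(ap * ap, bm * bm) + std::max(cp * cp, dm * dm));
        } else {
          const double am = a < 0 ? a : 0, bp = b > 0 ? b : 0;
          const double cm = c < 0 ? c : 0, dp_ = d > 0 ? d : 0;
          gm = std::sqrt(std::max(am * am, bp * bp) + std::max(cm * cm, dp_ * dp_));
        }
        upd(i, j) = sgn(i, j) * (1.0 - gm);
      }
    }
    for (int t = 0; t < n; ++t) phi[t] += dtau * upd[t];
  }
  return phi;
}
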