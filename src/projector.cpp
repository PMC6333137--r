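#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Image convention (shared with the R side): matrix row 1 is the anterior
// (top) edge, +y up; column j maps to x = (j - (nc+1)/2) * px, row i to
// y = ((nr+1)/2 - i) * px; world origin at isocenter. All lengths in cm.

static inline double bilinear(const double *img, int nr, int nc,
                              double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int ri = r0 + dr;
    if (ri < 0 || ri >= nr) continue;
    double wr = dr ? fr : 1.0 - fr;
    for (int dc = 0; dc <= 1; ++dc) {
      int ci = c0 + dc;
      if (ci < 0 || ci >= nc) continue;
      double wc = dc ? fc : 1.0 - fc;
      v += wr * wc * img[ci * nr + ri];
    }
  }
  return v;
}

static inline void splat(double *img, int nr, int nc,
                         double r, double c, double val) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  for (int dr = 0; dr <= 1; ++dr) {
    int ri = r0 + dr;
    if (ri < 0 || ri >= nr) continue;
    double wr = dr ? fr : 1.0 - fr;
    for (int dc = 0; dc <= 1; ++dc) {
      int ci = c0 + dc;
      if (ci < 0 || ci >= nc) continue;
      double wc = dc ? fc : 1.0 - fc;
      img[ci * nr + ri] += wr * wc * val;
    }
  }
}

// Ray-driven fan-beam forward projection over an equiangular detector.
// beta_k = 2*pi*k/n_views (CCW); source at sid*(-sin b, cos b); channel m has
// angle gamma = (m - (n_chan-1)/2) * pitch, rotating the central ray CCW.
// [[Rcpp::export(name = ".fp_fanbeam_cpp")]]
NumericMatrix fp_fanbeam_cpp(NumericMatrix image, double px, double sid,
                             int n_views, int n_chan, double pitch,
                             double step) {
  int nr = image.nrow(), nc = image.ncol();
  const double *img = REAL(image);
  NumericMatrix out(n_views, n_chan);
  double rimg = 0.5 * px * std::sqrt((double)nr * nr + (double)nc * nc) + px;
  double gamma0 = -0.5 * (n_chan - 1) * pitch;
  double cr = 0.5 * (nr - 1), cc = 0.5 * (nc - 1);
  for (int v = 0; v < n_views; ++v) {
    double beta = 2.0 * M_PI * v / n_views;
    double sx = -sid * std::sin(beta), sy = sid * std::cos(beta);
    double d0x = std::sin(beta), d0y = -std::cos(beta);
    for (int m = 0; m < n_chan; ++m) {
      double g = gamma0 + m * pitch;
      double cg = std::cos(g), sg = std::sin(g);
      double dx = d0x * cg - d0y * sg;
      double dy = d0x * sg + d0y * cg;
      double sd = sx * dx + sy * dy;
      double disc = sd * sd - (sid * sid - rimg * rimg);
      if (disc <= 0) { out(v, m) = 0.0; continue; }
      double t0 = -sd - std::sqrt(disc), t1 = -sd + std::sqrt(disc);
      int n = (int)std::ceil((t1 - t0) / step);
      if (n < 1) n = 1;
      double h = (t1 - t0) / n, acc = 0.0;
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * h;
        double x = sx + t * dx, y = sy + t * dy;
        acc += bilinear(img, nr, nc, cr - y / px, x / px + cc);
      }
      out(v, m) = acc * h;
    }
  }
  return out;
}

// Exact adjoint of fp_fanbeam_cpp (same sampling loop, transposed).
// [[Rcpp::export(name = ".bp_adjoint_cpp")]]
NumericMatrix bp_adjoint_cpp(NumericMatrix sino, int nr, int nc, double px,
                             double sid, double pitch, double step) {
  int n_views = sino.nrow(), n_chan = sino.ncol();
  NumericMatrix out(nr, nc);
  double *img = REAL(out);
  double rimg = 0.5 * px * std::sqrt((double)nr * nr + (double)nc * nc) + px;
  double gamma0 = -0.5 * (n_chan - 1) * pitch;
  double cr = 0.5 * (nr - 1), cc = 0.5 * (nc - 1);
  for (int v = 0; v < n_views; ++v) {
    double beta = 2.0 * M_PI * v / n_views;
    double sx = -sid * std::sin(beta), sy = sid * std::cos(beta);
    double d0x = std::sin(beta), d0y = -std::cos(beta);
    for (int m = 0; m < n_chan; ++m) {
      double val = sino(v, m);
      if (val == 0.0) continue;
      double g = gamma0 + m * pitch;
      double cg = std::cos(g), sg = std::sin(g);
      double dx = d0x * cg - d0y * sg;
      double dy = d0x * sg + d0y * cg;
      double sd = sx * dx + sy * dy;
      double disc = sd * sd - (sid * sid - rimg * rimg);
      if (disc <= 0) continue;
      double t0 = -sd - std::sqrt(disc), t1 = -sd + std::sqrt(disc);
      int n = (int)std::ceil((t1 - t0) / step);
      if (n < 1) n = 1;
      double h = (t1 - t0) / n;
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * h;
        double x = sx + t * dx, y = sy + t * dy;
        splat(img, nr, nc, cr - y / px, x / px + cc, val * h);
      }
    }
  }
  return out;
}

// Distance-weighted backprojection for equiangular fan-beam FBP.  q holds the
// cosine-weighted, ramp-filtered projections; the 1/L^2 weight and the view
// increment dbeta complete the Kak-Slaney reconstruction formula.
// [[Rcpp::export(name = ".fbp_backproject_cpp")]]
NumericMatrix fbp_backproject_cpp(NumericMatrix q, double sid, double pitch,
                                  int nr, int nc, double px) {
  int n_views = q.nrow(), n_chan = q.ncol();
  NumericMatrix out(nr, nc);
  double gamma0 = -0.5 * (n_chan - 1) * pitch;
  double dbeta = 2.0 * M_PI / n_views;
  std::vector<double> sxv(n_views), syv(n_views), d0xv(n_views), d0yv(n_views);
  for (int v = 0; v < n_views; ++v) {
    double beta = dbeta * v;
    sxv[v] = -sid * std::sin(beta);
    syv[v] = sid * std::cos(beta);
    d0xv[v] = std::sin(beta);
    d0yv[v] = -std::cos(beta);
  }
  for (int j = 0; j < nc; ++j) {
    double x = (j - 0.5 * (nc - 1)) * px;
    for (int i = 0; i < nr; ++i) {
      double y = (0.5 * (nr - 1) - i) * px;
      double acc = 0.0;
      for (int v = 0; v < n_views; ++v) {
        double vx = x - sxv[v], vy = y - syv[v];
        double L2 = vx * vx + vy * vy;
        double gp = std::atan2(d0xv[v] * vy - d0yv[v] * vx,
                               d0xv[v] * vx + d0yv[v] * vy);
        double c = (gp - gamma0) / pitch;
        if (c < 0.0 || c > n_chan - 1) continue;
        int c0 = (int)std::floor(c);
        if (c0 == n_chan - 1) c0 = n_chan - 2;
        double fc = c - c0;
        double qi = (1.0 - fc) * q(v, c0) + fc * q(v, c0 + 1);
        acc += qi / L2;
      }
      out(i, j) = acc * dbeta;
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution with an odd symmetric kernel, reflective boundary.
// [[Rcpp::export(name = ".sep_filter_cpp")]]
NumericMatrix sep_filter_cpp(NumericMatrix image, NumericVector kernel) {
  int nr = image.nrow(), nc = image.ncol();
  int klen = kernel.size(), rad = (klen - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k)
        acc += kernel[k + rad] * image(reflect_idx(i + k, nr), j);
      tmp(i, j) = acc;
    }
  // along columns (horizontal direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k)
        acc += kernel[k + rad] * tmp(i, reflect_idx(j + k, nc));
      out(i, j) = acc;
    }
  return out;
}
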