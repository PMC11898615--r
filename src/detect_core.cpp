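#include <Rcpp.h>
using namespace Rcpp;

// Separable negated-LoG response: d2_x(g_y(I)) + g_x(d2_y(I)), zero padding.
// g and d2 are the 1D kernel components (same odd length).
// [[Rcpp::export]]
NumericMatrix cpp_log_response(const NumericMatrix& img,
                               const NumericVector& g,
                               const NumericVector& d2) {
  const int ny = img.nrow(), nx = img.ncol();
  const int m = g.size(), h = (m - 1) / 2;
  NumericMatrix t1(ny, nx), t2(ny, nx), out(ny, nx);
  const double* pim = img.begin();
  double* p1 = t1.begin();
  double* p2 = t2.begin();
  double* po = out.begin();
  const double* pg = g.begin();
  const double* pd = d2.begin();
  // column (y) pass within each image column (contiguous)
  for (int j = 0; j < nx; ++j) {
    const double* col = pim + (size_t)j * ny;
    double* c1 = p1 + (size_t)j * ny;
    double* c2 = p2 + (size_t)j * ny;
    for (int i = 0; i < ny; ++i) {
      double s1 = 0.0, s2 = 0.0;
      const int a0 = std::max(0, i - h), a1 = std::min(ny - 1, i + h);
      const int k0 = a0 - i + h;
      const double* v = col + a0;
      const double* kg = pg + k0;
      const double* kd = pd + k0;
      for (int a = a0; a <= a1; ++a, ++v, ++kg, ++kd) {
        s1 += (*kg) * (*v);
        s2 += (*kd) * (*v);
      }
      c1[i] = s1;
      c2[i] = s2;
    }
  }
  // row (x) pass: out(:,j) = sum_b d2[k] t1(:,b) + g[k] t2(:,b), columnwise
  for (int j = 0; j < nx; ++j) {
    double* oc = po + (size_t)j * ny;
    const int b0 = std::max(0, j - h), b1 = std::min(nx - 1, j + h);
    for (int b = b0; b <= b1; ++b) {
      const int ki = b - j + h;
      const double wd = pd[ki], wg = pg[ki];
      const double* s1 = p1 + (size_t)b * ny;
      const double* s2 = p2 + (size_t)b * ny;
      for (int i = 0; i < ny; ++i) {
        oc[i] += wd * s1[i] + wg * s2[i];
      }
    }
  }
  return out;
}

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double m = v[n / 2];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
    m = 0.5 * (m + v[n / 2 - 1]);
  }
  return m;
}

// Local median and MAD in a (2*win+1)^2 window around each candidate
// (1-based row/col indices); returns an n x 2 matrix (median, mad).
// [[Rcpp::export]]
NumericMatrix cpp_local_stats(const NumericMatrix& img,
                              const IntegerVector& row,
                              const IntegerVector& col, int win) {
  const int ny = img.nrow(), nx = img.ncol(), n = row.size();
  NumericMatrix out(n, 2);
  std::vector<double> buf;
  buf.reserve((2 * win + 1) * (2 * win + 1));
  for (int s = 0; s < n; ++s) {
    const int r0 = std::max(1, row[s] - win), r1 = std::min(ny, row[s] + win);
    const int c0 = std::max(1, col[s] - win), c1 = std::min(nx, col[s] + win);
    buf.clear();
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) buf.push_back(img(r - 1, c - 1));
    const double med = median_of(buf);
    for (size_t i = 0; i < buf.size(); ++i) buf[i] = std::fabs(buf[i] - med);
    out(s, 0) = med;
    out(s, 1) = median_of(buf);
  }
  return out;
}

// Iterative Gaussian-weighted centroid refinement; r0, c0 are 1-based pixel
// indices of the current estimate; bg is subtracted before weighting.
// [[Rcpp::export]]
NumericVector cpp_centroid_refine(const NumericMatrix& img, double r0,
                                  double c0, double sigma, double bg,
                                  int maxit) {
  const int ny = img.nrow(), nx = img.ncol();
  const int h = std::max(2, (int)std::ceil(2.0 * sigma));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int it = 0; it < maxit; ++it) {
    const int r_lo = std::max(1, (int)std::floor(r0) - h);
    const int r_hi = std::min(ny, (int)std::ceil(r0) + h);
    const int c_lo = std::max(1, (int)std::floor(c0) - h);
    const int c_hi = std::min(nx, (int)std::ceil(c0) + h);
    double sw = 0.0, sr = 0.0, sc = 0.0;
    for (int c = c_lo; c <= c_hi; ++c) {
      const double wx = std::exp(-(c - c0) * (c - c0) * inv2s2);
      for (int r = r_lo; r <= r_hi; ++r) {
        double v = img(r - 1, c - 1) - bg;
        if (v <= 0.0) continue;
        const double w =
            wx * std::exp(-(r - r0) * (r - r0) * inv2s2) * v;
        sw += w;
        sr += w * r;
        sc += w * c;
      }
    }
    if (sw <= 0.0) break;
    const double r1 = sr / sw, c1 = sc / sw;
    const bool done = std::fabs(r1 - r0) < 1e-3 && std::fabs(c1 - c0) < 1e-3;
    r0 = r1;
    c0 = c1;
    if (done) break;
  }
  return NumericVector::create(r0, c0);
}
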