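#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Median RGB features on a regular pixel grid. `img` is an h x w x 3 array
// (values 0..255); the window is win x win centred on the grid position and
// clipped at the image border, so the median runs over the available pixels.
// Grid order matches expand.grid(y = seq(1, h, stride), x = seq(1, w, stride)):
// y varies fastest.
// [[Rcpp::export(name = ".grid_median_cpp")]]
NumericMatrix grid_median_cpp(NumericVector img, int stride, int win) {
  IntegerVector dims = img.attr("dim");
  const int h = dims[0], w = dims[1], nc = dims[2];
  const int half = win / 2;
  const int ny = (h + stride - 1) / stride;
  const int nx = (w + stride - 1) / stride;
  NumericMatrix out(ny * nx, nc);
  std::vector<double> buf;
  buf.reserve((size_t)win * win);
  int k = 0;
  for (int gx = 0; gx < nx; ++gx) {
    const int x = gx * stride;  // 0-based column
    const int x0 = std::max(0, x - half), x1 = std::min(w - 1, x + half);
    for (int gy = 0; gy < ny; ++gy, ++k) {
      const int y = gy * stride;
      const int y0 = std::max(0, y - half), y1 = std::min(h - 1, y + half);
      for (int c = 0; c < nc; ++c) {
        buf.clear();
        const double *ch = &img[(size_t)c * h * w];
        for (int xx = x0; xx <= x1; ++xx) {
          const double *col = ch + (size_t)xx * h;
          for (int yy = y0; yy <= y1; ++yy) buf.push_back(col[yy]);
        }
        const size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + n / 2 - 1,
                           buf.begin() + n / 2);
          med = (med + buf[n / 2 - 1]) / 2.0;
        }
        out(k, c) = med;
      }
    }
  }
  return out;
}

// Exhaustive best-matching unit: squared Euclidean distance over all
// prototypes, ties resolved to the lowest node id. 1-based ids.
// [[Rcpp::export(name = ".bmu_cpp")]]
IntegerVector bmu_cpp(NumericMatrix protos, NumericMatrix x) {
  const int m = protos.nrow(), d = protos.ncol(), n = x.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = x(i, c) - protos(j, c);
        s += diff * diff;
      }
      if (s < best) { best = s; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

static int argmin_node(const NumericMatrix &P, const double *x, int d,
                       const IntegerVector &pool) {
  double best = R_PosInf;
  int bj = pool[0];
  for (int k = 0; k < pool.size(); ++k) {
    const int j = pool[k] - 1;
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      const double diff = x[c] - P(j, c);
      s += diff * diff;
    }
    if (s < best) { best = s; bj = pool[k]; }
  }
  return bj;
}

// One growth phase of H2SOM training. The winner is found by beam descent:
// best node of ring 1, then best child of the current node per ring, ending in
// the ring being trained (depth = ring index). Only `active` (current-ring)
// prototypes are updated, weighted by a Gaussian kernel in the precomputed
// hyperbolic node distances D. Learning rate and kernel width decay
// exponentially from (a0, s0) to (a1, s1) across the phase.
// [[Rcpp::export(name = ".h2som_phase_cpp")]]
NumericMatrix h2som_phase_cpp(NumericMatrix x, NumericMatrix protos,
                              NumericMatrix D, IntegerVector ring1,
                              List children, int depth, IntegerVector active,
                              IntegerVector ord, double a0, double a1,
                              double s0, double s1) {
  NumericMatrix P = clone(protos);
  const int d = P.ncol();
  const int T = ord.size();
  std::vector<double> xi(d);
  for (int t = 0; t < T; ++t) {
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double alpha = a0 * std::pow(a1 / a0, frac);
    const double sigma = s0 * std::pow(s1 / s0, frac);
    const double denom = 2.0 * sigma * sigma;
    const int i = ord[t] - 1;
    for (int c = 0; c < d; ++c) xi[c] = x(i, c);
    int cur = argmin_node(P, xi.data(), d, ring1);
    for (int r = 2; r <= depth; ++r) {
      IntegerVector pool = children[cur - 1];
      if (pool.size() == 0) break;
      cur = argmin_node(P, xi.data(), d, pool);
    }
    for (int k = 0; k < active.size(); ++k) {
      const int j = active[k] - 1;
      const double dd = D(cur - 1, j);
      const double hker = std::exp(-(dd * dd) / denom);
      if (hker < 1e-4) continue;
      const double f = alpha * hker;
      for (int c = 0; c < d; ++c) P(j, c) += f * (xi[c] - P(j, c));
    }
  }
  return P;
}
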