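#include <Rcpp.h>
using namespace Rcpp;

// Deposit particles as pixel-integrated Gaussian spots on an np x np image
// (rows = y, cols = x).  For each particle the spot mass in pixel column c
// is erf-integrated over the pixel edges; the window is truncated at
// +/- hw pixels around the home pixel (callers size hw so the omitted
// tail mass is negligible).  Weights carry brightness x photon scale.

static const double INV_SQRT2 = 0.7071067811865476;

// [[Rcpp::export(name = ".deposit_spots_cpp")]]
NumericMatrix deposit_spots_cpp(NumericVector x, NumericVector y,
                                NumericVector w, int np, double ps,
                                double sigma, int hw) {
  int n = x.size();
  NumericMatrix img(np, np);
  int nw = 2 * hw + 1;
  std::vector<double> wx(nw), wy(nw), ex(nw + 1), ey(nw + 1);
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0) continue;
    int px = (int)std::floor(x[i] / ps);
    int py = (int)std::floor(y[i] / ps);
    // cumulative pixel-edge masses: window m spans edges m and m + 1
    for (int m = 0; m <= nw; ++m) {
      ex[m] = std::erf(((px + m - hw) * ps - x[i]) / sigma * INV_SQRT2);
      ey[m] = std::erf(((py + m - hw) * ps - y[i]) / sigma * INV_SQRT2);
    }
    for (int m = 0; m < nw; ++m) {
      wx[m] = 0.5 * (ex[m + 1] - ex[m]);
      wy[m] = 0.5 * (ey[m + 1] - ey[m]);
    }
    for (int mi = 0; mi < nw; ++mi) {
      int cx = px + mi - hw;
      if (cx < 0 || cx >= np) continue;
      double vx = w[i] * wx[mi];
      double *col = &img(0, cx);
      for (int mj = 0; mj < nw; ++mj) {
        int cy = py + mj - hw;
        if (cy < 0 || cy >= np) continue;
        col[cy] += vx * wy[mj];
      }
    }
  }
  return img;
}

// Paired deposit: two weight vectors over the same particle positions
// (e.g. a bleached stack and its unbleached control) share the erf work.
// [[Rcpp::export(name = ".deposit_spots2_cpp")]]
List deposit_spots2_cpp(NumericVector x, NumericVector y,
                        NumericVector w1, NumericVector w2, int np,
                        double ps, double sigma, int hw) {
  int n = x.size();
  NumericMatrix img1(np, np), img2(np, np);
  int nw = 2 * hw + 1;
  std::vector<double> wx(nw), wy(nw), ex(nw + 1), ey(nw + 1);
  for (int i = 0; i < n; ++i) {
    if (w1[i] <= 0 && w2[i] <= 0) continue;
    int px = (int)std::floor(x[i] / ps);
    int py = (int)std::floor(y[i] / ps);
    for (int m = 0; m <= nw; ++m) {
      ex[m] = std::erf(((px + m - hw) * ps - x[i]) / sigma * INV_SQRT2);
      ey[m] = std::erf(((py + m - hw) * ps - y[i]) / sigma * INV_SQRT2);
    }
    for (int m = 0; m < nw; ++m) {
      wx[m] = 0.5 * (ex[m + 1] - ex[m]);
      wy[m] = 0.5 * (ey[m + 1] - ey[m]);
    }
    for (int mi = 0; mi < nw; ++mi) {
      int cx = px + mi - hw;
      if (cx < 0 || cx >= np) continue;
      double v1 = w1[i] * wx[mi], v2 = w2[i] * wx[mi];
      double *c1 = &img1(0, cx), *c2 = &img2(0, cx);
      for (int mj = 0; mj < nw; ++mj) {
        int cy = py + mj - hw;
        if (cy < 0 || cy >= np) continue;
        c1[cy] += v1 * wy[mj];
        c2[cy] += v2 * wy[mj];
      }
    }
  }
  return List::create(img1, img2);
}
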