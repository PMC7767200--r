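#include <Rcpp.h>
using namespace Rcpp;

// Brownian substeps among impermeable reflecting discs.
//
// Per substep and particle: propose a Gaussian step, reflect at the box
// walls, then (a) if the endpoint lies inside a disc, mirror it across the
// disc boundary (reject if the mirrored point is blocked or outside), and
// (b) if the step midpoint lies inside a disc, reject the move.  The cell
// lookup stores up to two candidate discs per cell (exact for disjoint
// discs at the grid resolution used); the exact distance test decides.
// Uses R's RNG, so results are reproducible under set.seed().

static inline double fold1(double x, double L) {
  double p = 2.0 * L;
  x -= p * std::floor(x / p);          // into [0, 2L)
  return L - std::fabs(x - L);
}

struct DiscField {
  const int *ids1, *ids2;
  const double *dx, *dy, *dr;
  double res;
  int ncell;
};

static inline int cell_of(const DiscField &f, double x, double y) {
  int ix = (int)(x / f.res);
  int iy = (int)(y / f.res);
  if (ix < 0) ix = 0; else if (ix >= f.ncell) ix = f.ncell - 1;
  if (iy < 0) iy = 0; else if (iy >= f.ncell) iy = f.ncell - 1;
  return ix + iy * f.ncell;            // column-major: ids(ix, iy)
}

// id (1-based) of the disc containing (x, y), or 0
static inline int disc_containing(const DiscField &f, double x, double y) {
  int cell = cell_of(f, x, y);
  for (int layer = 0; layer < 2; ++layer) {
    int id = layer == 0 ? f.ids1[cell] : f.ids2[cell];
    if (id > 0) {
      double ddx = x - f.dx[id - 1], ddy = y - f.dy[id - 1];
      if (ddx * ddx + ddy * ddy < f.dr[id - 1] * f.dr[id - 1]) return id;
    }
  }
  return 0;
}

// [[Rcpp::export(name = ".obstructed_steps_cpp")]]
NumericMatrix obstructed_steps_cpp(NumericMatrix pos, int n_sub, double sd1,
                                   NumericVector disc_x, NumericVector disc_y,
                                   NumericVector disc_r, IntegerMatrix ids,
                                   IntegerMatrix ids2, double res, int ncell,
                                   double L) {
  int n = pos.nrow();
  NumericMatrix p = clone(pos);
  DiscField f = {INTEGER(ids), INTEGER(ids2),
                 REAL(disc_x), REAL(disc_y), REAL(disc_r), res, ncell};
  RNGScope scope;
  for (int s = 0; s < n_sub; ++s) {
    for (int i = 0; i < n; ++i) {
      double x0 = p(i, 0), y0 = p(i, 1);
      // Box-Muller pair on R's uniform stream: cheaper than the inversion
      // method of norm_rand(), equally deterministic under set.seed()
      double u1 = unif_rand(), u2 = unif_rand();
      double rad = std::sqrt(-2.0 * std::log(u1));
      double ang = 6.283185307179586 * u2;
      double x1 = fold1(x0 + rad * std::cos(ang) * sd1, L);
      double y1 = fold1(y0 + rad * std::sin(ang) * sd1, L);
      // endpoint inside a disc: mirror across the boundary
      int id = disc_containing(f, x1, y1);
      if (id > 0) {
        double cx = disc_x[id - 1], cy = disc_y[id - 1], r = disc_r[id - 1];
        double ddx = x1 - cx, ddy = y1 - cy;
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        if (d < 1e-12) { continue; }            // degenerate: reject
        double sc = (2.0 * r - d) / d;
        double mx = cx + ddx * sc, my = cy + ddy * sc;
        if (mx < 0 || mx > L || my < 0 || my > L ||
            disc_containing(f, mx, my) > 0) {
          continue;                             // blocked: reject the move
        }
        x1 = mx; y1 = my;
      }
      // step passes through a disc (midpoint inside): reject
      if (disc_containing(f, 0.5 * (x0 + x1), 0.5 * (y0 + y1)) > 0) {
        continue;
      }
      p(i, 0) = x1;
      p(i, 1) = y1;
    }
  }
  return p;
}
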