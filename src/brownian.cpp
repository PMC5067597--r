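#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama Brownian walk in the vesicle-lattice cell (all lengths in um).
// Vesicles are spheres of radius r resting on the plane z = 0 at centers
// (cx, cy, r).  Absorbing sets: the ribbon band of each sphere (surface points
// with z <= eps) and the top plane z = ztop (entry into the undifferentiated
// bulk).  Reflecting: the base plane, the sphere surfaces above the ribbon and
// the lateral walls of the tiled region.  The per-axis step s.d. is adapted to
// the distance from the nearest absorbing feature but never exceeds eps/5 next
// to a sphere, so the ribbon cannot be jumped over.
//
// outcome code: 0 = bulk, 1..NT = ribbon of that vesicle, -1 = censored.
static int walk_one(double x, double y, double z,
                    const NumericMatrix &centers, double r, double eps,
                    double ztop, const double *bounds,
                    double smin, double smax, int max_steps,
                    std::mt19937_64 &rng,
                    std::normal_distribution<double> &gauss) {
  const int nc = centers.nrow();
  for (int step = 0; step < max_steps; ++step) {
    double dmin = ztop - z;
    for (int j = 0; j < nc; ++j) {
      double dx = x - centers(j, 0), dy = y - centers(j, 1), dz = z - r;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - r;
      if (d < dmin) dmin = d;
    }
    double s = dmin / 3.0;
    if (s < smin) s = smin;
    if (s > smax) s = smax;
    x += s * gauss(rng);
    y += s * gauss(rng);
    z += s * gauss(rng);
    if (z < 0) z = -z;
    if (z >= ztop) return 0;
    if (x < bounds[0]) x = 2 * bounds[0] - x;
    if (x > bounds[1]) x = 2 * bounds[1] - x;
    if (y < bounds[2]) y = 2 * bounds[2] - y;
    if (y > bounds[3]) y = 2 * bounds[3] - y;
    for (int j = 0; j < nc; ++j) {
      double dx = x - centers(j, 0), dy = y - centers(j, 1), dz = z - r;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < r * r) {
        double d = std::sqrt(d2);
        if (d < 1e-12) d = 1e-12;
        double zq = r + r * dz / d; // radial projection onto the surface
        if (zq <= eps) return j + 1;
        double f = (2 * r - d) / d; // mirror across the sphere surface
        x = centers(j, 0) + dx * f;
        y = centers(j, 1) + dy * f;
        z = r + dz * f;
        if (z < 0) z = -z;
      }
    }
  }
  return -1;
}

// Raw outcomes for trajectories launched from a single membrane position.
// [[Rcpp::export]]
IntegerVector brw_trajectories(double x0, double y0, NumericMatrix centers,
                               double r, double eps, double ztop,
                               NumericVector bounds, int nruns,
                               double smin, double smax, int max_steps,
                               int seed) {
  IntegerVector res(nruns);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double b[4] = {bounds[0], bounds[1], bounds[2], bounds[3]};
  for (int i = 0; i < nruns; ++i)
    res[i] = walk_one(x0, y0, 1e-9, centers, r, eps, ztop, b, smin, smax,
                      max_steps, rng, gauss);
  return res;
}

// Outcome counts for a batch of launch points (one row per point):
// columns = bulk, target 1..NT, censored.
// [[Rcpp::export]]
IntegerMatrix brw_outcome_counts(NumericVector xs, NumericVector ys,
                                 int runs_per_point, NumericMatrix centers,
                                 double r, double eps, double ztop,
                                 NumericVector bounds,
                                 double smin, double smax, int max_steps,
                                 int seed) {
  const int np = xs.size(), nc = centers.nrow();
  IntegerMatrix counts(np, nc + 2);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double b[4] = {bounds[0], bounds[1], bounds[2], bounds[3]};
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < runs_per_point; ++i) {
      int out = walk_one(xs[p], ys[p], 1e-9, centers, r, eps, ztop, b,
                         smin, smax, max_steps, rng, gauss);
      if (out < 0)
        counts(p, nc + 1)++;
      else
        counts(p, out)++;
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
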