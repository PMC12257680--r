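#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming solver for the elastic warping problem on a uniform
// grid of the unit interval. Finds the monotone, endpoint-preserving lattice
// path gamma minimizing
//   integral (mu(t) - q(gamma(t)) sqrt(gamma'(t)))^2 dt
//     + lambda * integral (sqrt(gamma'(t)) - 1)^2 dt
// over paths with segment slopes in [1/5, 5]. Segment costs are accumulated
// with the trapezoid rule at the source-grid resolution; q is evaluated off
// the grid by linear interpolation. Ties are broken toward the segment whose
// slope is closest to 1 (smallest warp deviation).

static inline double interp_q(const NumericVector& q, double x, int n) {
  // x in index units [0, n-1]
  if (x <= 0) return q[0];
  if (x >= n - 1) return q[n - 1];
  int i = (int)std::floor(x);
  double w = x - i;
  return (1.0 - w) * q[i] + w * q[i + 1];
}

// [[Rcpp::export(name = ".dp_warp_cpp")]]
NumericVector dp_warp_cpp(NumericVector mu, NumericVector q, double lambda) {
  const int n = mu.size();
  if (q.size() != n) stop("mu and q must share a grid");
  if (n < 3) stop("need at least 3 grid points");
  const double h = 1.0 / (n - 1);

  // candidate segment offsets (di, dj): coprime pairs up to 7 whose slopes
  // dj/di lie in the window [1/5, 5]
  const int max_step = 7;
  std::vector<int> DI, DJ;
  for (int di = 1; di <= max_step; ++di) {
    for (int dj = 1; dj <= max_step; ++dj) {
      double slope = (double)dj / (double)di;
      if (slope < 0.2 - 1e-12 || slope > 5.0 + 1e-12) continue;
      int a = di, b = dj;
      while (b) { int t = a % b; a = b; b = t; }
      if (a == 1) { DI.push_back(di); DJ.push_back(dj); }
    }
  }
  const int nmoves = DI.size();
  const double INF = std::numeric_limits<double>::infinity();

  NumericMatrix E(n, n);       // accumulated cost to reach (i, j)
  IntegerMatrix PI(n, n), PJ(n, n);
  std::fill(E.begin(), E.end(), INF);
  E(0, 0) = 0.0;

  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = INF, best_dev = INF;
      int bi = -1, bj = -1;
      for (int m = 0; m < nmoves; ++m) {
        int pi = i - DI[m], pj = j - DJ[m];
        if (pi < 0 || pj < 0) continue;
        double prev = E(pi, pj);
        if (!std::isfinite(prev)) continue;
        double slope = (double)DJ[m] / (double)DI[m];
        double sq = std::sqrt(slope);
        // trapezoid over the di sub-steps of the segment
        double c0 = mu[pi] - interp_q(q, (double)pj, n) * sq;
        double seg = 0.0;
        for (int s = 1; s <= DI[m]; ++s) {
          double gj = pj + slope * s;
          double c1 = mu[pi + s] - interp_q(q, gj, n) * sq;
          seg += 0.5 * (c0 * c0 + c1 * c1) * h;
          c0 = c1;
        }
        seg += lambda * (sq - 1.0) * (sq - 1.0) * DI[m] * h;
        double cost = prev + seg;
        double dev = std::fabs(slope - 1.0);
        if (cost < best - 1e-12 ||
            (std::fabs(cost - best) <= 1e-12 && dev < best_dev)) {
          best = cost; best_dev = dev; bi = pi; bj = pj;
        }
      }
      E(i, j) = best;
      PI(i, j) = bi;
      PJ(i, j) = bj;
    }
  }
  if (!std::isfinite(E(n - 1, n - 1))) stop("no feasible warping path");

  // backtrack the path, then expand to gamma on the full grid
  std::vector<int> pathi, pathj;
  int ci = n - 1, cj = n - 1;
  while (ci > 0 || cj > 0) {
    pathi.push_back(ci); pathj.push_back(cj);
    int ni = PI(ci, cj), nj = PJ(ci, cj);
    ci = ni; cj = nj;
  }
  pathi.push_back(0); pathj.push_back(0);

  NumericVector gamma(n);
  for (int k = (int)pathi.size() - 1; k > 0; --k) {
    int i0 = pathi[k], j0 = pathj[k];
    int i1 = pathi[k - 1], j1 = pathj[k - 1];
    double slope = (double)(j1 - j0) / (double)(i1 - i0);
    for (int s = 0; s <= i1 - i0; ++s) {
      gamma[i0 + s] = (j0 + slope * s) * h;
    }
  }
  gamma[0] = 0.0;
  gamma[n - 1] = 1.0;
  return gamma;
}
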