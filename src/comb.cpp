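#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Comb membership convention used throughout: a signed projection x belongs to
// the comb with spacing d iff the nearest nonzero node n*d (1 <= |n| <=
// floor(qmax/d)) satisfies |x - n*d| <= eps.  Since d > 2*eps the qualifying
// node, when it exists, is unique.

static inline int node_max(double d, double qmax) {
  return (int)std::floor(qmax / d * (1.0 + 1e-12));
}

static inline bool comb_member(double x, double d, double eps, int nmax) {
  if (nmax < 1) return false;
  double p = std::fabs(x);
  int k = (int)std::lround(p / d);
  if (k < 1) k = 1;
  if (k > nmax) k = nmax;
  return std::fabs(p - k * d) <= eps;
}

// Batch scan: for each direction (row of U), count comb members of the
// projected g-vectors at every spacing of the adaptive grid, subtract the
// random-placement background bg, and report the best spacing.  The count
// profile over the grid is built by interval accumulation: point p is a member
// via harmonic n exactly for d in [(p-eps)/n, min((p+eps)/n, qmax/n)], so each
// (point, harmonic) pair contributes one increment range on the grid.
// Returns an M x 3 matrix: best dstar, raw count, score (ties -> larger d*).
// [[Rcpp::export]]
NumericMatrix cpp_scan_dirs(const NumericMatrix& G, const NumericMatrix& U,
                            const NumericVector& grid, const NumericVector& bg,
                            double eps, double qmax) {
  const int N = G.nrow(), M = U.nrow(), J = grid.size();
  if (bg.size() != J) stop("grid/background length mismatch");
  NumericMatrix out(M, 3);
  std::vector<int> diff((size_t)J + 1);
  const double gmin = grid[0], gmaxv = grid[J - 1];
  const double* gr = grid.begin();
  // uniform-bin index into the (irregular) grid: binStart[b] is the first
  // grid index whose value reaches the start of bin b, so a lower/upper
  // bound query only has to walk the few grid points inside one bin
  const int K = 2 * J;
  const double bs = (gmaxv - gmin) / K;
  std::vector<int> binStart((size_t)K + 2);
  {
    int j = 0;
    for (int b = 0; b <= K + 1; ++b) {
      double edge = gmin + b * bs;
      while (j < J && gr[j] < edge) ++j;
      binStart[b] = j;
    }
  }
  auto firstGE = [&](double x) {  // first grid index with grid >= x
    if (x <= gmin) return 0;
    if (x > gmaxv) return J;
    int b = (int)((x - gmin) / bs);
    if (b > K) b = K;
    int j = binStart[b];
    while (j < J && gr[j] < x) ++j;
    return j;
  };
  auto lastLE = [&](double x) {  // last grid index with grid <= x
    if (x < gmin) return -1;
    if (x >= gmaxv) return J - 1;
    int b = (int)((x - gmin) / bs) + 1;
    if (b > K + 1) b = K + 1;
    int j = binStart[b];
    while (j > 0 && gr[j - 1] > x) --j;
    return j - 1;
  };
  for (int m = 0; m < M; ++m) {
    std::fill(diff.begin(), diff.end(), 0);
    const double ux = U(m, 0), uy = U(m, 1), uz = U(m, 2);
    for (int i = 0; i < N; ++i) {
      double p = std::fabs(G(i, 0) * ux + G(i, 1) * uy + G(i, 2) * uz);
      int nhi = (int)std::floor((p + eps) / gmin);
      for (int n = 1; n <= nhi; ++n) {
        double lo = (p - eps) / n;
        double hi = (p + eps) / n;
        double hq = qmax / n * (1.0 + 1e-12);
        if (hi > hq) hi = hq;
        if (hi < gmin || lo > gmaxv) continue;
        int jlo = firstGE(lo);
        int jhi = lastLE(hi);
        if (jlo > jhi) continue;
        diff[jlo]++;
        diff[jhi + 1]--;
      }
    }
    int cnt = 0, bestj = -1, bestc = 0;
    double bests = -1e300;
    for (int j = 0; j < J; ++j) {
      cnt += diff[j];
      double s = cnt - bg[j];
      if (s >= bests) { bests = s; bestj = j; bestc = cnt; }
    }
    out(m, 0) = grid[bestj];
    out(m, 1) = bestc;
    out(m, 2) = bests;
  }
  return out;
}

// Counts for explicit (direction, spacing) pairs; used by the local grid
// refinement where the spacing is off the adaptive grid.
// [[Rcpp::export]]
IntegerVector cpp_count_pairs(const NumericMatrix& G, const NumericMatrix& U,
                              const NumericVector& dstars, double eps,
                              double qmax) {
  const int N = G.nrow(), K = U.nrow();
  IntegerVector out(K);
  for (int k = 0; k < K; ++k) {
    const double ux = U(k, 0), uy = U(k, 1), uz = U(k, 2), d = dstars[k];
    const int nmax = node_max(d, qmax);
    int cnt = 0;
    for (int i = 0; i < N; ++i) {
      double x = G(i, 0) * ux + G(i, 1) * uy + G(i, 2) * uz;
      if (comb_member(x, d, eps, nmax)) ++cnt;
    }
    out[k] = cnt;
  }
  return out;
}

// Counts for one fixed projection set at many candidate spacings.
// [[Rcpp::export]]
IntegerVector cpp_count_multi(const NumericVector& proj,
                              const NumericVector& dstars, double eps,
                              double qmax) {
  const int N = proj.size(), K = dstars.size();
  IntegerVector out(K);
  for (int k = 0; k < K; ++k) {
    const double d = dstars[k];
    const int nmax = node_max(d, qmax);
    int cnt = 0;
    for (int i = 0; i < N; ++i)
      if (comb_member(proj[i], d, eps, nmax)) ++cnt;
    out[k] = cnt;
  }
  return out;
}

// integral of (q^2 - x^2)+ over [a, b], 0 <= a <= b
static inline double quad_int_pos(double a, double b, double q) {
  if (a > q) a = q;
  if (b > q) b = q;
  return (q * q * b - b * b * b / 3.0) - (q * q * a - a * a * a / 3.0);
}

// expected comb count for n points uniform in the shell [qmin, qmax]
static double shell_background(int n, double d, double eps, double qmin,
                               double qmax) {
  int nmax = node_max(d, qmax);
  if (nmax < 1) return 0.0;
  double s = 0.0;
  for (int k = 1; k <= nmax; ++k) {
    double c = k * d;
    double a = c - eps;
    if (a < 0) a = 0;
    s += quad_int_pos(a, c + eps, qmax) - quad_int_pos(a, c + eps, qmin);
  }
  return n * 2.0 * 3.0 * s / (4.0 * (qmax * qmax * qmax -
                                     qmin * qmin * qmin));
}

// Iterative least-squares snap of (direction, spacing) pairs onto the 1-D
// lattice suggested by their own comb membership: members get node numbers
// n_i = round(x_i / d); the minimizer y of sum (g_i . y - n_i)^2 gives the
// refined direction y/|y| and spacing 1/|y|; membership is re-collected and
// the fit repeated while the background-subtracted score improves.
// Returns an M x 6 matrix: ux, uy, uz, dstar, count, score.
// [[Rcpp::export]]
NumericMatrix cpp_snap_ls(const NumericMatrix& G, const NumericMatrix& U,
                          const NumericVector& D, double eps, double qmin,
                          double qmax, double dmin, double dmax,
                          int maxIter, bool includeOrigin = false) {
  const int N = G.nrow(), M = U.nrow();
  NumericMatrix out(M, 6);
  for (int m = 0; m < M; ++m) {
    double u[3] = {U(m, 0), U(m, 1), U(m, 2)};
    double d = D[m];
    double bu[3] = {u[0], u[1], u[2]};
    double bd = d;
    int bcount = -1;
    double bscore = -1e300;
    for (int it = 0; it <= maxIter; ++it) {
      int nmax = node_max(d, qmax);
      double ata[6] = {0, 0, 0, 0, 0, 0};  // xx, xy, xz, yy, yz, zz
      double atb[3] = {0, 0, 0};
      int cnt = 0;
      for (int i = 0; i < N; ++i) {
        double gx = G(i, 0), gy = G(i, 1), gz = G(i, 2);
        double x = gx * u[0] + gy * u[1] + gz * u[2];
        double p = std::fabs(x);
        int k = (int)std::lround(p / d);
        if (k < 1) k = includeOrigin ? 0 : 1;
        if (k > nmax) k = nmax;
        if (nmax < 1 || std::fabs(p - k * d) > eps) continue;
        ++cnt;
        double n = (x < 0) ? -k : k;
        ata[0] += gx * gx; ata[1] += gx * gy; ata[2] += gx * gz;
        ata[3] += gy * gy; ata[4] += gy * gz; ata[5] += gz * gz;
        atb[0] += n * gx; atb[1] += n * gy; atb[2] += n * gz;
      }
      double bgv = shell_background(N, d, eps, qmin, qmax);
      if (includeOrigin)
        bgv += N * 2.0 * 3.0 * (quad_int_pos(0, eps, qmax) -
                                quad_int_pos(0, eps, qmin)) /
               (4.0 * (qmax * qmax * qmax - qmin * qmin * qmin));
      double score = cnt - bgv;
      bool improved = score > bscore;
      if (improved) {
        bscore = score; bcount = cnt; bd = d;
        bu[0] = u[0]; bu[1] = u[1]; bu[2] = u[2];
      }
      if (it == maxIter || cnt < 3 || (it > 0 && !improved)) break;
      // solve ata * y = atb (3x3 symmetric, Cramer)
      double det = ata[0] * (ata[3] * ata[5] - ata[4] * ata[4]) -
                   ata[1] * (ata[1] * ata[5] - ata[4] * ata[2]) +
                   ata[2] * (ata[1] * ata[4] - ata[3] * ata[2]);
      if (std::fabs(det) < 1e-30) break;
      double y0 = (atb[0] * (ata[3] * ata[5] - ata[4] * ata[4]) -
                   ata[1] * (atb[1] * ata[5] - ata[4] * atb[2]) +
                   ata[2] * (atb[1] * ata[4] - ata[3] * atb[2])) / det;
      double y1 = (ata[0] * (atb[1] * ata[5] - atb[2] * ata[4]) -
                   atb[0] * (ata[1] * ata[5] - ata[4] * ata[2]) +
                   ata[2] * (ata[1] * atb[2] - atb[1] * ata[2])) / det;
      double y2 = (ata[0] * (ata[3] * atb[2] - ata[4] * atb[1]) -
                   ata[1] * (ata[1] * atb[2] - atb[1] * ata[2]) +
                   atb[0] * (ata[1] * ata[4] - ata[3] * ata[2])) / det;
      double len = std::sqrt(y0 * y0 + y1 * y1 + y2 * y2);
      if (!(len > 0)) break;
      double d2 = 1.0 / len;
      if (d2 <= 2 * eps || d2 < dmin || d2 > dmax) break;
      u[0] = y0 / len; u[1] = y1 / len; u[2] = y2 / len;
      d = d2;
    }
    out(m, 0) = bu[0]; out(m, 1) = bu[1]; out(m, 2) = bu[2];
    out(m, 3) = bd; out(m, 4) = bcount; out(m, 5) = bscore;
  }
  return out;
}

// Greedy antipodal-equivalent deduplication of unit directions: keep a row if
// |dot| with every previously kept row is below cosThresh.  Returns 1-based
// indices of kept rows.
// [[Rcpp::export]]
IntegerVector cpp_dedup_dirs(const NumericMatrix& U, double cosThresh) {
  const int M = U.nrow();
  std::vector<int> keep;
  keep.reserve(256);
  for (int m = 0; m < M; ++m) {
    bool dup = false;
    for (size_t j = 0; j < keep.size(); ++j) {
      int k = keep[j];
      double dot = U(m, 0) * U(k, 0) + U(m, 1) * U(k, 1) + U(m, 2) * U(k, 2);
      if (std::fabs(dot) >= cosThresh) { dup = true; break; }
    }
    if (!dup) keep.push_back(m);
  }
  IntegerVector out(keep.size());
  for (size_t j = 0; j < keep.size(); ++j) out[j] = keep[j] + 1;
  return out;
}

// For each query point (row of P) find the nearest row of G.
// Returns a list with 1-based indices and Euclidean distances.
// [[Rcpp::export]]
List cpp_nearest(const NumericMatrix& P, const NumericMatrix& G) {
  const int L = P.nrow(), A = G.nrow();
  IntegerVector idx(L);
  NumericVector dist(L);
  for (int l = 0; l < L; ++l) {
    const double px = P(l, 0), py = P(l, 1), pz = P(l, 2);
    double best = 1e300;
    int bi = -1;
    for (int a = 0; a < A; ++a) {
      double dx = G(a, 0) - px, dy = G(a, 1) - py, dz = G(a, 2) - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = a; }
    }
    idx[l] = bi + 1;
    dist[l] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
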