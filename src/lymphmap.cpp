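#include <Rcpp.h>
using namespace Rcpp;

// Column-major raw-pointer distance between point i of X (n rows) and
// centre c of C (k rows), p features.
static inline double pt_dist2(const double* X, int n, int i, const double* C,
                              int k, int c, int p) {
  double d = 0.0;
  for (int j = 0; j < p; ++j) {
    double t = X[(size_t)j * n + i] - C[(size_t)j * k + c];
    d += t * t;
  }
  return d;
}

// k-means++ seeding. Uses R's RNG so results follow set.seed(). If the
// residual distance mass hits zero before k centres are chosen the data has
// fewer than k distinct points; the attribute "degenerate" reports it.
// [[Rcpp::export]]
NumericMatrix cpp_kmeanspp_init(NumericMatrix X, int k) {
  int n = X.nrow(), p = X.ncol();
  const double* x = REAL(X);
  NumericMatrix centers(k, p);
  double* cen = REAL(centers);
  std::vector<double> d2(n);
  bool degenerate = false;

  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  for (int j = 0; j < p; ++j) cen[(size_t)j * k] = x[(size_t)j * n + first];
  for (int i = 0; i < n; ++i) d2[i] = pt_dist2(x, n, i, cen, k, 0, p);

  for (int c = 1; c < k; ++c) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += d2[i];
    int pick;
    if (total <= 0.0) {
      degenerate = true;
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * total, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    for (int j = 0; j < p; ++j)
      cen[(size_t)j * k + c] = x[(size_t)j * n + pick];
    for (int i = 0; i < n; ++i) {
      double d = pt_dist2(x, n, i, cen, k, c, p);
      if (d < d2[i]) d2[i] = d;
    }
  }
  centers.attr("degenerate") = degenerate;
  return centers;
}

// Lloyd's algorithm. Ties in the nearest-centroid assignment go to the
// lowest cluster index; empty clusters keep their previous centroid. Stops
// when the largest centroid displacement falls below tol or after max_iter
// sweeps. The three-feature case (water/fat/STIR) is unrolled.
// [[Rcpp::export]]
List cpp_lloyd(NumericMatrix X, NumericMatrix init, int max_iter, double tol) {
  int n = X.nrow(), p = X.ncol(), k = init.nrow();
  const double* x = REAL(X);
  NumericMatrix centers = clone(init);
  double* cen = REAL(centers);
  IntegerVector assign(n);
  int* asg = INTEGER(assign);
  std::vector<double> sums((size_t)k * p);
  std::vector<int> counts(k);
  double wcss = 0.0;
  int iter;

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(counts.begin(), counts.end(), 0);
    if (p == 3) {
      const double *x0 = x, *x1 = x + n, *x2 = x + 2 * (size_t)n;
      const double *c0 = cen, *c1 = cen + k, *c2 = cen + 2 * (size_t)k;
      for (int i = 0; i < n; ++i) {
        double v0 = x0[i], v1 = x1[i], v2 = x2[i];
        int best = 0;
        double bd = R_PosInf;
        for (int c = 0; c < k; ++c) {
          double t0 = v0 - c0[c], t1 = v1 - c1[c], t2 = v2 - c2[c];
          double d = t0 * t0 + t1 * t1 + t2 * t2;
          if (d < bd) { bd = d; best = c; }
        }
        asg[i] = best;
        counts[best]++;
        sums[best] += v0; sums[best + k] += v1; sums[best + 2 * k] += v2;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        int best = 0;
        double bd = pt_dist2(x, n, i, cen, k, 0, p);
        for (int c = 1; c < k; ++c) {
          double d = pt_dist2(x, n, i, cen, k, c, p);
          if (d < bd) { bd = d; best = c; }
        }
        asg[i] = best;
        counts[best]++;
        for (int j = 0; j < p; ++j) sums[(size_t)j * k + best] += x[(size_t)j * n + i];
      }
    }
    double shift = 0.0;
    for (int c = 0; c < k; ++c) {
      if (counts[c] == 0) continue;  // empty cluster: centroid unchanged
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        double nc = sums[(size_t)j * k + c] / counts[c];
        double t = nc - cen[(size_t)j * k + c];
        s += t * t;
        cen[(size_t)j * k + c] = nc;
      }
      shift = std::max(shift, std::sqrt(s));
    }
    if (shift < tol) break;
  }

  // final assignment/WCSS against the converged centroids
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = pt_dist2(x, n, i, cen, k, 0, p);
    for (int c = 1; c < k; ++c) {
      double d = pt_dist2(x, n, i, cen, k, c, p);
      if (d < bd) { bd = d; best = c; }
    }
    asg[i] = best + 1;
    wcss += bd;
  }

  return List::create(_["centers"] = centers, _["cluster"] = assign,
                      _["wcss"] = wcss, _["iter"] = std::min(iter, max_iter));
}

// Nearest-centroid assignment (1-based), ties to the lowest cluster index.
// [[Rcpp::export]]
IntegerVector cpp_assign(NumericMatrix X, NumericMatrix centers) {
  int n = X.nrow(), p = X.ncol(), k = centers.nrow();
  const double* x = REAL(X);
  const double* cen = REAL(centers);
  IntegerVector out(n);
  int* o = INTEGER(out);
  if (p == 3) {
    const double *x0 = x, *x1 = x + n, *x2 = x + 2 * (size_t)n;
    const double *c0 = cen, *c1 = cen + k, *c2 = cen + 2 * (size_t)k;
    for (int i = 0; i < n; ++i) {
      double v0 = x0[i], v1 = x1[i], v2 = x2[i];
      int best = 0;
      double bd = R_PosInf;
      for (int c = 0; c < k; ++c) {
        double t0 = v0 - c0[c], t1 = v1 - c1[c], t2 = v2 - c2[c];
        double d = t0 * t0 + t1 * t1 + t2 * t2;
        if (d < bd) { bd = d; best = c; }
      }
      o[i] = best + 1;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      int best = 0;
      double bd = pt_dist2(x, n, i, cen, k, 0, p);
      for (int c = 1; c < k; ++c) {
        double d = pt_dist2(x, n, i, cen, k, c, p);
        if (d < bd) { bd = d; best = c; }
      }
      o[i] = best + 1;
    }
  }
  return out;
}

// For each query point (rows of Q, integer grid coordinates), the squared
// Euclidean distance to the nearest point in T. Exact; used for the
// midcontour (epifascial layer) split where ties must be detected exactly.
// [[Rcpp::export]]
NumericVector cpp_min_dist2(IntegerMatrix Q, IntegerMatrix T) {
  int nq = Q.nrow(), nt = T.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int qx = Q(i, 0), qy = Q(i, 1);
    for (int j = 0; j < nt; ++j) {
      double dx = qx - T(j, 0), dy = qy - T(j, 1);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
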