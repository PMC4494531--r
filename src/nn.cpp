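#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact brute-force nearest neighbour between 3D point sets (rows).

// [[Rcpp::export]]
List nn1_cpp(NumericMatrix query, NumericMatrix ref) {
  R_xlen_t nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != 3 || ref.ncol() != 3) stop("points must be n x 3");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf; R_xlen_t bj = 0;
    for (R_xlen_t j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = (int)(bj + 1);
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Inverse-distance-weighted mean of ref values within `radius` of each query
// point; count of contributing neighbours returned alongside (0 = unlabeled).

// [[Rcpp::export]]
List idw_radius_cpp(NumericMatrix query, NumericMatrix ref,
                    NumericVector value, double radius) {
  R_xlen_t nq = query.nrow(), nr = ref.nrow();
  if (ref.nrow() != value.size()) stop("value length must match ref rows");
  NumericVector out(nq);
  IntegerVector cnt(nq);
  double r2 = radius * radius;
  const double eps = 1e-12;
  for (R_xlen_t i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double num = 0.0, den = 0.0, exact = 0.0;
    int k = 0;
    bool has_exact = false;
    for (R_xlen_t j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) {
        ++k;
        double d = std::sqrt(d2);
        if (d < eps && !has_exact) { has_exact = true; exact = value[j]; }
        num += value[j] / std::max(d, eps);
        den += 1.0 / std::max(d, eps);
      }
    }
    cnt[i] = k;
    if (k == 0) out[i] = NA_REAL;
    else out[i] = has_exact ? exact : num / den;
  }
  return List::create(_["value"] = out, _["count"] = cnt);
}
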