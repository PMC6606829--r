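#include <Rcpp.h>
using namespace Rcpp;

// Local similarity dynamic program over aligned positions with offset
// |i - j| <= D:
//   P(i,j) = max(0, P(i-1,j-1) + x_i * y_j)
//   N(i,j) = max(0, N(i-1,j-1) - x_i * y_j)
// The score is the maximal cell over P and N divided by n; the sign is
// negative when the maximum comes from N. The delay is the offset j - i of
// the maximizing alignment; ties prefer the smallest |delay|, then the
// positive delay. Offsets are scanned in that preference order so a strict
// ">" keeps the preferred candidate.

static void scan_offset(const NumericVector& x, const NumericVector& y,
                        int d, double& best, int& best_sign,
                        int& best_delay) {
  // alignment x[i] with y[i + d]
  int n = x.size();
  int i0 = std::max(0, -d);
  int i1 = std::min(n, n - d);
  double p = 0.0, q = 0.0;
  for (int i = i0; i < i1; ++i) {
    double prod = x[i] * y[i + d];
    p = std::max(0.0, p + prod);
    q = std::max(0.0, q - prod);
    if (p > best) { best = p; best_sign = 1; best_delay = d; }
    if (q > best) { best = q; best_sign = -1; best_delay = d; }
  }
}

// [[Rcpp::export(name = ".lsa_score_cpp")]]
List lsa_score_cpp(NumericVector x, NumericVector y, int max_delay) {
  if (x.size() != y.size()) stop("series length mismatch");
  int n = x.size();
  double best = 0.0;
  int best_sign = 1, best_delay = 0;
  for (int a = 0; a <= max_delay; ++a) {
    scan_offset(x, y, a, best, best_sign, best_delay);
    if (a > 0) scan_offset(x, y, -a, best, best_sign, best_delay);
  }
  return List::create(_["score"] = best / n,
                      _["sign"] = best_sign,
                      _["delay"] = best_delay);
}

// |score| for each row of a permutation-index matrix applied to y
// (indices are 1-based, from R)
// [[Rcpp::export(name = ".lsa_perm_scores_cpp")]]
NumericVector lsa_perm_scores_cpp(NumericVector x, NumericVector y,
                                  int max_delay, IntegerMatrix perms) {
  int n = x.size();
  int nperm = perms.nrow();
  NumericVector out(nperm);
  NumericVector yp(n);
  for (int k = 0; k < nperm; ++k) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(k, i) - 1];
    double best = 0.0;
    int s = 1, d0 = 0;
    for (int a = 0; a <= max_delay; ++a) {
      scan_offset(x, yp, a, best, s, d0);
      if (a > 0) scan_offset(x, yp, -a, best, s, d0);
    }
    out[k] = best / n;
  }
  return out;
}
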