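#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular two-sample statistic over all arcs (i+1)..j of x.
// Constraints: the arc and its complement are both >= min_width bins,
// and any flanking piece left behind by the split is either empty or
// >= min_width bins. Ties are broken to the smallest (i, then j).
static void max_stat_scan(const double* x, int n, int min_width,
                          double* best_stat, int* best_i, int* best_j) {
  *best_stat = -1.0;
  *best_i = -1;
  *best_j = -1;
  std::vector<double> S(n + 1);
  S[0] = 0.0;
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double tot = S[n];
  for (int k = min_width; k <= n - min_width; ++k) {
    const double denom = std::sqrt(1.0 / k + 1.0 / (n - k));
    for (int i = 0; i <= n - k; ++i) {
      const int left = i, right = n - i - k;
      if (left != 0 && left < min_width) continue;
      if (right != 0 && right < min_width) continue;
      const double arc = S[i + k] - S[i];
      double stat = std::fabs(arc / k - (tot - arc) / (n - k)) / denom;
      const int j = i + k;
      if (stat > *best_stat + 1e-12 ||
          (stat > *best_stat - 1e-12 &&
           (i < *best_i || (i == *best_i && j < *best_j)))) {
        *best_stat = stat;
        *best_i = i;
        *best_j = j;
      }
    }
  }
}

// true as soon as any admissible arc reaches `threshold`
static bool any_stat_reaches(const double* x, int n, int min_width,
                             double threshold) {
  std::vector<double> S(n + 1);
  S[0] = 0.0;
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double tot = S[n];
  for (int k = min_width; k <= n - min_width; ++k) {
    const double denom = std::sqrt(1.0 / k + 1.0 / (n - k));
    const double bar = threshold * denom;
    for (int i = 0; i <= n - k; ++i) {
      const int left = i, right = n - i - k;
      if (left != 0 && left < min_width) continue;
      if (right != 0 && right < min_width) continue;
      const double arc = S[i + k] - S[i];
      if (std::fabs(arc / k - (tot - arc) / (n - k)) >= bar) return true;
    }
  }
  return false;
}

// [[Rcpp::export(.cbs_max_stat_cpp)]]
List cbs_max_stat_cpp(NumericVector x, int min_width) {
  int n = x.size();
  if (n < 2 * min_width) return List::create();
  double stat;
  int i, j;
  max_stat_scan(REAL(x), n, min_width, &stat, &i, &j);
  return List::create(_["stat"] = stat, _["i"] = i, _["j"] = j);
}

// Permutation test with early stopping: permutes x (R's RNG, so seeded
// runs reproduce), counts permuted maxima reaching the observed value,
// and stops as soon as the p-value can no longer fall below alpha.
// [[Rcpp::export(.cbs_perm_p_cpp)]]
double cbs_perm_p_cpp(NumericVector x, double obs, double alpha, int nperm,
                      int min_width) {
  int n = x.size();
  NumericVector work = clone(x);
  int exceed = 0;
  const double threshold = obs - 1e-12;
  for (int b = 1; b <= nperm; ++b) {
    // Fisher-Yates with R's RNG
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(work[t], work[u]);
    }
    if (any_stat_reaches(REAL(work), n, min_width, threshold)) {
      ++exceed;
      if (exceed + 1 >= alpha * (nperm + 1)) {
        return (double)(exceed + 1) / (nperm + 1);
      }
    }
  }
  return (double)(exceed + 1) / (nperm + 1);
}
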