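#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Minimum observed-significance statistic over the K nested subsets of the
// s smallest p-values (equivalent to the minimum over all nonzero binary
// weight vectors by monotone optimality of the weighted Fisher statistic).
static double min_u_sorted(double *p, int K) {
  std::sort(p, p + K);
  double cum = 0.0, best = 1.0;
  for (int s = 0; s < K; ++s) {
    cum += -2.0 * std::log(p[s]);
    double u = R::pchisq(cum, 2.0 * (s + 1), 0, 0);
    if (u < best) best = u;
  }
  return best;
}

//' Null sample of the AW-Fisher minimum observed-significance statistic.
//'
//' Draws B vectors of K i.i.d. Uniform(0,1) p-values (R's RNG stream) and
//' returns min over nonzero binary weight vectors of the chi-square
//' upper-tail probability of the weighted Fisher statistic.
//'
//' @param B number of null draws
//' @param K number of studies
//' @return numeric vector of length B
// [[Rcpp::export]]
NumericVector aw_null_sample(int B, int K) {
  NumericVector out(B);
  std::vector<double> p(K);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) p[k] = unif_rand();
    out[b] = min_u_sorted(p.data(), K);
  }
  return out;
}

//' Count null draws with minimum statistic at or below a threshold.
//'
//' Memory-free variant of aw_null_sample for very large B: counts
//' draws whose min-U statistic is <= t_obs.
//'
//' @param B number of null draws
//' @param K number of studies
//' @param t_obs observed minimum statistic
//' @return integer count (as double, B may exceed INT_MAX in sums)
// [[Rcpp::export]]
double aw_null_count_le(double B, int K, double t_obs) {
  double hits = 0.0;
  std::vector<double> p(K);
  double Bn = B;
  for (double b = 0; b < Bn; b += 1.0) {
    for (int k = 0; k < K; ++k) p[k] = unif_rand();
    if (min_u_sorted(p.data(), K) <= t_obs) hits += 1.0;
  }
  return hits;
}
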