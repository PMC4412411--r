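#include <Rcpp.h>
using namespace Rcpp;

// Final associative strengths of the Rescorla-Wagner (model = 1) and
// Pearce-Hall (model = 2) learners for a stacked set of rounds, mirroring
// assoc_round() in R/models.R. lambda holds the per-trial outcome magnitude
// normalised to [0,1]; salience grows as min(1, sal_c * cumulative
// presentations).
// [[Rcpp::export]]
NumericMatrix assoc_strengths_cpp(IntegerMatrix counts, IntegerVector firsts,
                                  IntegerVector lasts, NumericVector lambda,
                                  int n_rounds, int n_trials, int model,
                                  double gamma0, double sal_c, double dp,
                                  double dr, bool sole) {
  const int k = counts.ncol();
  NumericMatrix out(n_rounds, k);
  std::vector<double> V(k), cum(k), u(k);
  for (int r = 0; r < n_rounds; ++r) {
    std::fill(V.begin(), V.end(), 0.0);
    std::fill(cum.begin(), cum.end(), 0.0);
    double gamma_ph = 1.0;  // initial surprise maximal for novel stimuli
    for (int t = 0; t < n_trials; ++t) {
      const int row = r * n_trials + t;
      double Vtot = 0.0;
      const double lam = lambda[row];
      for (int i = 0; i < k; ++i) {
        double x = counts(row, i);
        u[i] = sole ? (x > 0.0 ? 1.0 : 0.0) : x;
        if (x > 0.0) Vtot += V[i];
        cum[i] += x;
      }
      u[firsts[row] - 1] += dp;
      u[lasts[row] - 1] += dr;
      for (int i = 0; i < k; ++i) {
        if (counts(row, i) == 0) continue;
        double sal = sal_c * cum[i];
        if (sal > 1.0) sal = 1.0;
        if (model == 1)
          V[i] += sal * u[i] * gamma0 * (lam - Vtot);
        else
          V[i] += sal * u[i] * gamma0 * gamma_ph * lam;
      }
      // surprise against the prediction held when the outcome arrived
      if (model == 2) gamma_ph = std::min(std::fabs(lam - Vtot), 1.0);
    }
    for (int i = 0; i < k; ++i) out(r, i) = V[i];
  }
  return out;
}
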