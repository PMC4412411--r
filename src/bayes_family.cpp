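#include <Rcpp.h>
using namespace Rcpp;

// Final causal strengths of the Dirichlet causal-inference learner for a
// stacked set of rounds. Mirrors run_bayes_family() in R/models.R: one belief
// per outcome type, rates read from the novel-outcome belief at the start of
// each trial, congruent +/incongruent - updates floored at zero. Only the
// end-of-round posterior mean of the novel-outcome belief is returned, which
// is all the SSE objective needs; the R implementation records the full
// trajectory and is cross-checked against this one in the test suite.
//
// variant: 1 = Bayes (constant rate), 2 = BayesM (softmax over mean),
//          3 = BayesU (softmax over variance)
// [[Rcpp::export]]
NumericMatrix bayes_strengths_cpp(IntegerMatrix counts, IntegerVector firsts,
                                  IntegerVector lasts, LogicalVector novel,
                                  int n_rounds, int n_trials, int variant,
                                  double gamma0, double tau, double dp,
                                  double dr, bool sole, NumericVector prior) {
  const int k = counts.ncol();
  NumericMatrix strengths(n_rounds, k);
  std::vector<double> a_nov(k), a_non(k), rates(k), mod(k), w(k), delta(k);

  for (int r = 0; r < n_rounds; ++r) {
    for (int i = 0; i < k; ++i) { a_nov[i] = prior[i]; a_non[i] = prior[i]; }
    for (int t = 0; t < n_trials; ++t) {
      const int row = r * n_trials + t;
      // modulating signal from the novel-outcome belief
      double a0 = 0.0;
      for (int i = 0; i < k; ++i) a0 += a_nov[i];
      if (variant == 1) {
        for (int i = 0; i < k; ++i) rates[i] = gamma0;
      } else {
        if (a0 <= 0.0) {
          for (int i = 0; i < k; ++i) mod[i] = 0.0;  // degenerate: uniform
        } else if (variant == 2) {
          for (int i = 0; i < k; ++i) mod[i] = a_nov[i] / a0;
        } else {
          for (int i = 0; i < k; ++i)
            mod[i] = a_nov[i] * (a0 - a_nov[i]) / (a0 * a0 * (a0 + 1.0));
        }
        double m = mod[0];
        for (int i = 1; i < k; ++i) if (mod[i] > m) m = mod[i];
        double s = 0.0;
        for (int i = 0; i < k; ++i) { w[i] = std::exp(tau * (mod[i] - m)); s += w[i]; }
        for (int i = 0; i < k; ++i) rates[i] = gamma0 * k * w[i] / s;
      }
      // trial update
      for (int i = 0; i < k; ++i) {
        double x = counts(row, i);
        if (sole && x > 0.0) x = 1.0;
        double bonus = 0.0;
        if (firsts[row] == i + 1) bonus += dp;
        if (lasts[row] == i + 1) bonus += dr;
        delta[i] = rates[i] * (x + bonus);
      }
      const bool nov = novel[row];
      for (int i = 0; i < k; ++i) {
        double an = a_nov[i] + (nov ? delta[i] : -delta[i]);
        double am = a_non[i] + (nov ? -delta[i] : delta[i]);
        a_nov[i] = an > 0.0 ? an : 0.0;
        a_non[i] = am > 0.0 ? am : 0.0;
      }
    }
    double a0 = 0.0;
    for (int i = 0; i < k; ++i) a0 += a_nov[i];
    for (int i = 0; i < k; ++i)
      strengths(r, i) = a0 > 0.0 ? a_nov[i] / a0 : 0.0;
  }
  return strengths;
}
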