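// Closed-loop QUEST session: staircase placement, generative observer
// response, Bayesian posterior update. Mirrors the R-level quest_*()
// arithmetic exactly (same grid, same cumulative-Gaussian likelihood);
// equivalence is asserted in the test suite by replaying recorded sessions
// through quest_update().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".run_session_cpp")]]
List run_session_cpp(int std_n, int n_trials, NumericVector grid,
                     NumericVector prior, double beta, double delta,
                     double gamma, double jitter, double b, double s,
                     double lapse, bool has_conj, double p_conj) {
  const int G = grid.size();
  NumericVector post = clone(prior);
  IntegerVector test_n(n_trials);
  LogicalVector resp(n_trials);
  NumericVector pm_v(n_trials);
  LogicalVector int_first(n_trials);
  LogicalVector ctgt(n_trials), ccor(n_trials);

  int lo = (int)std::lround(std_n / 3.0);
  if (lo < 2) lo = 2;
  const int hi = 3 * std_n;

  for (int t = 0; t < n_trials; ++t) {
    double sum = 0.0, m = 0.0;
    for (int g = 0; g < G; ++g) {
      sum += post[g];
      m += grid[g] * post[g];
    }
    const double pm = m / sum;

    const double j = jitter > 0 ? R::runif(-jitter, jitter) : 0.0;
    int tn = (int)std::lround(std_n * std::pow(10.0, pm + j));
    if (tn < lo) tn = lo;
    if (tn > hi) tn = hi;
    if (tn == std_n) {                  // equal comparison is uninformative
      const int dir = (j >= 0) ? 1 : -1;
      tn += dir;
      if (tn < lo) tn = lo;
      if (tn > hi) tn = hi;
      if (tn == std_n) tn = std_n - dir;
    }

    bool r;
    if (lapse > 0 && R::unif_rand() < lapse) {
      r = R::unif_rand() < 0.5;
    } else {
      // common noise scale s * standard_n for both percepts
      const double p_std = std::max(0.01, R::rnorm(b * std_n, s * std_n));
      const double p_tst = std::max(0.01, R::rnorm((double)tn, s * std_n));
      r = p_tst > p_std;
    }

    const double x = std::log10((double)tn / std_n);
    double ss = 0.0;
    for (int g = 0; g < G; ++g) {
      const double psi =
          gamma + (1.0 - gamma - delta) *
                      R::pnorm((x - grid[g]) / beta, 0.0, 1.0, 1, 0);
      post[g] *= r ? psi : 1.0 - psi;
      ss += post[g];
    }
    for (int g = 0; g < G; ++g) post[g] /= ss;

    test_n[t] = tn;
    resp[t] = r;
    pm_v[t] = pm;
    int_first[t] = R::unif_rand() < 0.5;
    if (has_conj) {
      ctgt[t] = R::unif_rand() < 0.5;
      ccor[t] = R::unif_rand() < p_conj;
    }
  }

  return List::create(_["test_n"] = test_n, _["response"] = resp,
                      _["posterior_mean"] = pm_v,
                      _["interval_first"] = int_first,
                      _["conj_target"] = ctgt, _["conj_correct"] = ccor);
}
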