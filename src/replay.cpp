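#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Trial-by-trial replay of the asymmetric Q-learning model over an
// observed choice/outcome sequence.  Trials must arrive grouped by
// context instance and ordered by context trial; a change in `instance`
// resets both Q-values to 0 and clears the perseveration state.
// choice: 0 = option A, 1 = option B.  r_u is NaN when the forgone
// outcome was not shown (partial feedback): the counterfactual update is
// then skipped.

static inline void replay_core(const IntegerVector& instance,
                               const IntegerVector& choice,
                               const NumericVector& r_c,
                               const NumericVector& r_u,
                               double beta, double acp, double acm,
                               double aup, double aum, double pi_w,
                               double* nll_out, double* p_a_out) {
  const int n = instance.size();
  double qA = 0.0, qB = 0.0, nll = 0.0;
  int prev = -1;
  int cur_inst = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || instance[t] != cur_inst) {
      cur_inst = instance[t];
      qA = qB = 0.0;
      prev = -1;
    }
    const double bA = (prev == 0) ? pi_w : 0.0;
    const double bB = (prev == 1) ? pi_w : 0.0;
    const double dA = beta * (qA + bA);
    const double dB = beta * (qB + bB);
    const double m = std::max(dA, dB);
    const double lZ = m + std::log(std::exp(dA - m) + std::exp(dB - m));
    const int c = choice[t];
    nll -= (c == 0 ? dA : dB) - lZ;
    if (p_a_out) p_a_out[t] = std::exp(dA - lZ);
    double& qc = (c == 0) ? qA : qB;
    const double pe = r_c[t] - qc;
    qc += (pe > 0 ? acp : acm) * pe;
    if (!ISNAN(r_u[t])) {
      double& qu = (c == 0) ? qB : qA;
      const double peu = r_u[t] - qu;
      qu += (peu > 0 ? aup : aum) * peu;
    }
    prev = c;
  }
  if (nll_out) *nll_out = nll;
}

// [[Rcpp::export]]
double nll_replay_cpp(IntegerVector instance, IntegerVector choice,
                      NumericVector r_c, NumericVector r_u,
                      double beta, double acp, double acm,
                      double aup, double aum, double pi_w) {
  double nll = 0.0;
  replay_core(instance, choice, r_c, r_u, beta, acp, acm, aup, aum, pi_w,
              &nll, nullptr);
  return nll;
}

// [[Rcpp::export]]
NumericVector prob_replay_cpp(IntegerVector instance, IntegerVector choice,
                              NumericVector r_c, NumericVector r_u,
                              double beta, double acp, double acm,
                              double aup, double aum, double pi_w) {
  NumericVector p_a(instance.size());
  replay_core(instance, choice, r_c, r_u, beta, acp, acm, aup, aum, pi_w,
              nullptr, REAL(p_a));
  return p_a;
}
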