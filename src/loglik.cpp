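#include <Rcpp.h>
using namespace Rcpp;

// Model ids: 1 = pvl_delta, 2 = pvl_decay, 3 = vpp.
// Parameter layout: pvl_*: (A, alpha, cons, lambda);
// vpp: (A, alpha, cons, lambda, epP, epN, K, w).

static inline double pv_utility(double x, double alpha, double lambda) {
  if (x >= 0.0) return std::pow(x, alpha);
  return -lambda * std::pow(-x, alpha);
}

// Per-trial log-likelihood of observed choices. `choice` is 1-based deck
// index, `net` the rescaled net outcome per trial. State starts at E = P = 0
// so the first trial is uniform; the observed choice's probability is
// evaluated before the state update.
// [[Rcpp::export]]
NumericVector cpp_seq_loglik(IntegerVector choice, NumericVector net,
                             NumericVector pars, int model) {
  const int n = choice.size();
  if (net.size() != n) stop("choice/net length mismatch");
  const double A = pars[0], alpha = pars[1], cons = pars[2], lambda = pars[3];
  double epP = 0.0, epN = 0.0, K = 0.0, w = 1.0;
  if (model == 3) {
    epP = pars[4]; epN = pars[5]; K = pars[6]; w = pars[7];
  }
  const double theta = std::pow(3.0, cons) - 1.0;

  double E[4] = {0, 0, 0, 0}, P[4] = {0, 0, 0, 0}, V[4];
  NumericVector ll(n);

  for (int t = 0; t < n; ++t) {
    const int c = choice[t] - 1;
    if (c < 0 || c > 3) stop("deck index out of range");
    for (int j = 0; j < 4; ++j)
      V[j] = (model == 3) ? w * E[j] + (1.0 - w) * P[j] : E[j];
    double m = theta * V[0];
    for (int j = 1; j < 4; ++j) m = std::max(m, theta * V[j]);
    double denom = 0.0;
    for (int j = 0; j < 4; ++j) denom += std::exp(theta * V[j] - m);
    ll[t] = theta * V[c] - m - std::log(denom);

    const double x = net[t];
    const double u = pv_utility(x, alpha, lambda);
    if (model == 2) {
      for (int j = 0; j < 4; ++j) E[j] *= A;
      E[c] += u;
    } else {
      E[c] += A * (u - E[c]);
    }
    if (model == 3) {
      for (int j = 0; j < 4; ++j) P[j] *= K;
      P[c] += (x >= 0.0) ? epP : epN;
    }
  }
  return ll;
}
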