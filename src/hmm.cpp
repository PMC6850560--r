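// Sequential per-step maximum-likelihood decomposition of a fluorescence (or
// binned spike-count) trace into onset indicator s, exponentially decaying
// transient level c, and random-walk baseline b. Pure function of the input
// trace and parameters; no RNG.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".hmm_decompose")]]
List hmm_decompose(NumericVector x, double dt, double q, double decay,
                   double sigma_x, double sigma_B, double sigma_C) {
  int n = x.size();
  IntegerVector s(n);
  NumericVector c(n), b(n);
  s[0] = 0; c[0] = 0.0; b[0] = x[0];
  const double vx = sigma_x * sigma_x;
  const double vB = sigma_B * sigma_B * dt;
  const double vC = sigma_C * sigma_C;
  const double dec = std::exp(-decay * dt);
  const double lqdt = std::log(q * dt);
  const double l1mq = std::log1p(-q * dt);
  const double lnormC = -0.5 * std::log(2.0 * M_PI * vC);
  const double shrink = 1.0 / (1.0 + vB / vC + vx / vC);
  for (int k = 1; k < n; ++k) {
    double cstar = c[k - 1] * dec;
    double bprev = b[k - 1];
    double r = x[k] - cstar - bprev;
    // s = 0: transient decays deterministically, baseline absorbs residual
    double b0 = ((x[k] - cstar) / vx + bprev / vB) / (1.0 / vx + 1.0 / vB);
    double lg0 = -0.5 * (x[k] - cstar - b0) * (x[k] - cstar - b0) / vx
                 -0.5 * (b0 - bprev) * (b0 - bprev) / vB;
    // s = 1: transient absorbs most of the residual
    double c1 = cstar + r * shrink;
    double b1 = bprev + (vB / vC) * (c1 - cstar);
    double lg1 = lnormC
                 -0.5 * (x[k] - c1 - b1) * (x[k] - c1 - b1) / vx
                 -0.5 * (b1 - bprev) * (b1 - bprev) / vB
                 -0.5 * (c1 - cstar) * (c1 - cstar) / vC;
    if (lqdt + lg1 > l1mq + lg0) {
      s[k] = 1; c[k] = c1; b[k] = b1;
    } else {
      s[k] = 0; c[k] = cstar; b[k] = b0;
    }
  }
  return List::create(_["s"] = s, _["c"] = c, _["b"] = b);
}
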