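#include <Rcpp.h>
using namespace Rcpp;

// Recurrent forward pass of a five-layer neuro-fuzzy network over a series.
//
// All indices are 0-based (converted by the R wrapper).  Layer 2 nodes are
// Gaussian membership functions with a recurrent self-link: the input of
// set s at step t is x[var(s)] + beta[s] * psi[s](t-1), where psi is the
// node's previous output (zero at t = 0).  Layer 3 rules take the product
// of their precondition memberships, layer 4 sums firing strengths per
// output node, and layer 5 is a width-weighted average of output centers.
//
// When the defuzzification denominator underflows below denom_floor the
// prediction falls back to the consequent center of the maximally firing
// rule; the number of such steps is returned in attribute "n_floored".
// [[Rcpp::export]]
NumericVector enfrn_forward_cpp(NumericMatrix x,
                                IntegerVector var_of_set,
                                NumericVector set_center,
                                NumericVector set_width,
                                NumericVector feedback,
                                IntegerMatrix rule_pre,
                                IntegerVector rule_out,
                                NumericVector out_center,
                                NumericVector out_width,
                                NumericVector state0,
                                double denom_floor) {
  const int T = x.nrow();
  const int K = x.ncol();
  const int S = set_center.size();
  const int R = rule_pre.nrow();
  const int O = out_center.size();

  NumericVector y(T);
  std::vector<double> psi(S), psi_prev(S), firing(R), act(O);
  for (int s = 0; s < S; ++s) psi_prev[s] = state0[s];
  int n_floored = 0;

  for (int t = 0; t < T; ++t) {
    // layer 2: recurrence-adjusted Gaussian memberships
    for (int s = 0; s < S; ++s) {
      double phi = x(t, var_of_set[s]) + feedback[s] * psi_prev[s];
      double z = (phi - set_center[s]) / set_width[s];
      psi[s] = std::exp(-z * z);
    }
    // layer 3: product AND over each rule's precondition sets
    for (int r = 0; r < R; ++r) {
      double f = 1.0;
      for (int k = 0; k < K; ++k) f *= psi[rule_pre(r, k)];
      firing[r] = f;
    }
    // layer 4: aggregate firing per output node
    for (int o = 0; o < O; ++o) act[o] = 0.0;
    for (int r = 0; r < R; ++r) act[rule_out[r]] += firing[r];
    // layer 5: width-weighted average of output centers
    double num = 0.0, den = 0.0;
    for (int o = 0; o < O; ++o) {
      num += out_width[o] * out_center[o] * act[o];
      den += out_width[o] * act[o];
    }
    if (den < denom_floor) {
      int best = 0;
      for (int r = 1; r < R; ++r) if (firing[r] > firing[best]) best = r;
      y[t] = out_center[rule_out[best]];
      ++n_floored;
    } else {
      y[t] = num / den;
    }
    std::swap(psi, psi_prev);
  }

  y.attr("n_floored") = n_floored;
  y.attr("state") = NumericVector(psi_prev.begin(), psi_prev.end());
  return y;
}
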