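#include <Rcpp.h>
using namespace Rcpp;

// Two-state hidden Markov model with binomial emissions over per-site
// (meth, total) counts. Scaled forward/backward recursions; the scaling
// factors give the log-likelihood. State order is whatever `p` encodes;
// canonicalisation (p_open > p_closed) happens on the R side.

static inline double emit(int m, int n, double p) {
  // n == 0 carries no information: emission probability 1 in both states
  return R::dbinom((double)m, (double)n, p, 0);
}

// [[Rcpp::export(name = ".bhmm_forward_backward")]]
List bhmm_forward_backward(IntegerVector meth, IntegerVector total,
                           NumericVector p, NumericMatrix trans,
                           NumericVector init) {
  int n = meth.size();
  if (n == 0) stop("empty observation sequence");
  NumericMatrix gamma(n, 2);
  std::vector<double> a0(n), a1(n), scale(n), e0(n), e1(n);
  for (int i = 0; i < n; i++) {
    e0[i] = emit(meth[i], total[i], p[0]);
    e1[i] = emit(meth[i], total[i], p[1]);
  }
  a0[0] = init[0] * e0[0];
  a1[0] = init[1] * e1[0];
  scale[0] = a0[0] + a1[0];
  if (scale[0] <= 0) stop("zero forward probability at site 1");
  a0[0] /= scale[0]; a1[0] /= scale[0];
  for (int i = 1; i < n; i++) {
    a0[i] = (a0[i-1] * trans(0,0) + a1[i-1] * trans(1,0)) * e0[i];
    a1[i] = (a0[i-1] * trans(0,1) + a1[i-1] * trans(1,1)) * e1[i];
    scale[i] = a0[i] + a1[i];
    if (scale[i] <= 0) stop("zero forward probability at site %d", i + 1);
    a0[i] /= scale[i]; a1[i] /= scale[i];
  }
  std::vector<double> b0(n), b1(n);
  b0[n-1] = 1.0; b1[n-1] = 1.0;
  for (int i = n - 2; i >= 0; i--) {
    b0[i] = (trans(0,0) * e0[i+1] * b0[i+1] + trans(0,1) * e1[i+1] * b1[i+1]) / scale[i+1];
    b1[i] = (trans(1,0) * e0[i+1] * b0[i+1] + trans(1,1) * e1[i+1] * b1[i+1]) / scale[i+1];
  }
  for (int i = 0; i < n; i++) {
    double g0 = a0[i] * b0[i], g1 = a1[i] * b1[i];
    double s = g0 + g1;
    gamma(i, 0) = g0 / s;
    gamma(i, 1) = g1 / s;
  }
  NumericMatrix xi(2, 2);
  for (int i = 0; i < n - 1; i++) {
    xi(0,0) += a0[i] * trans(0,0) * e0[i+1] * b0[i+1] / scale[i+1];
    xi(0,1) += a0[i] * trans(0,1) * e1[i+1] * b1[i+1] / scale[i+1];
    xi(1,0) += a1[i] * trans(1,0) * e0[i+1] * b0[i+1] / scale[i+1];
    xi(1,1) += a1[i] * trans(1,1) * e1[i+1] * b1[i+1] / scale[i+1];
  }
  double ll = 0.0;
  for (int i = 0; i < n; i++) ll += std::log(scale[i]);
  // expected binomial sufficient statistics per state
  NumericVector meth_w(2), total_w(2);
  for (int i = 0; i < n; i++) {
    meth_w[0] += gamma(i,0) * meth[i];  total_w[0] += gamma(i,0) * total[i];
    meth_w[1] += gamma(i,1) * meth[i];  total_w[1] += gamma(i,1) * total[i];
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi,
                      _["meth_w"] = meth_w, _["total_w"] = total_w);
}

// [[Rcpp::export(name = ".bhmm_viterbi")]]
List bhmm_viterbi(IntegerVector meth, IntegerVector total,
                  NumericVector p, NumericMatrix trans,
                  NumericVector init) {
  int n = meth.size();
  if (n == 0) stop("empty observation sequence");
  std::vector<double> d0(n), d1(n);
  std::vector<int> bp0(n), bp1(n);
  double lt00 = std::log(trans(0,0)), lt01 = std::log(trans(0,1));
  double lt10 = std::log(trans(1,0)), lt11 = std::log(trans(1,1));
  d0[0] = std::log(init[0]) + R::dbinom((double)meth[0], (double)total[0], p[0], 1);
  d1[0] = std::log(init[1]) + R::dbinom((double)meth[0], (double)total[0], p[1], 1);
  for (int i = 1; i < n; i++) {
    double le0 = R::dbinom((double)meth[i], (double)total[i], p[0], 1);
    double le1 = R::dbinom((double)meth[i], (double)total[i], p[1], 1);
    double f00 = d0[i-1] + lt00, f10 = d1[i-1] + lt10;
    double f01 = d0[i-1] + lt01, f11 = d1[i-1] + lt11;
    if (f00 >= f10) { d0[i] = f00 + le0; bp0[i] = 0; }
    else            { d0[i] = f10 + le0; bp0[i] = 1; }
    if (f01 >= f11) { d1[i] = f01 + le1; bp1[i] = 0; }
    else            { d1[i] = f11 + le1; bp1[i] = 1; }
  }
  IntegerVector states(n);
  double best;
  if (d0[n-1] >= d1[n-1]) { states[n-1] = 0; best = d0[n-1]; }
  else                    { states[n-1] = 1; best = d1[n-1]; }
  for (int i = n - 2; i >= 0; i--) {
    states[i] = (states[i+1] == 0) ? bp0[i+1] : bp1[i+1];
  }
  return List::create(_["states"] = states, _["logprob"] = best);
}
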