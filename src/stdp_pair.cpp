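#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multiplicative pair STDP on a single synapse, all-to-all pairing via two
// exponential traces (exact for exponential windows). Events are processed in
// time order; simultaneous pre/post spikes contribute nothing to each other
// (both branches of the rule require a strict time difference), and when a
// pre and a post event share a time stamp the post-triggered update is
// applied first. With freeze = true the multiplicative factors are held at
// their w0 values and the accumulated (unclipped) change is returned; this is
// the linearized drift used in the mean-field theory.
// [[Rcpp::export]]
List stdp_pair_cpp(NumericVector pre, NumericVector post, double w0,
                   double a_plus, double a_minus,
                   double tau_plus, double tau_minus,
                   double w_max, bool freeze) {
  const int np = pre.size(), nq = post.size();
  double w = w0, dw_sum = 0.0;
  double x = 0.0, y = 0.0;          // pre / post traces
  double tx = 0.0, ty = 0.0;        // their last-update times
  int i = 0, j = 0;
  auto clip = [&](double val) {
    return val < 0 ? 0.0 : (val > w_max ? w_max : val);
  };
  while (i < np || j < nq) {
    bool tie = i < np && j < nq && pre[i] == post[j];
    bool take_post = j < nq && (i >= np || post[j] <= pre[i]);
    if (tie) {
      double t = post[j];
      double x_t = x * std::exp(-(t - tx) / tau_plus);
      double y_t = y * std::exp(-(t - ty) / tau_minus);
      if (freeze) {
        dw_sum += a_plus * x_t * (w_max - w0) + a_minus * y_t * w0;
      } else {
        w = clip(w + a_plus * x_t * (w_max - w));
        w = clip(w + a_minus * y_t * w);
      }
      x = x_t + 1.0; tx = t;
      y = y_t + 1.0; ty = t;
      ++i; ++j;
    } else if (take_post) {
      double t = post[j];
      double x_t = x * std::exp(-(t - tx) / tau_plus);
      if (freeze) dw_sum += a_plus * x_t * (w_max - w0);
      else w = clip(w + a_plus * x_t * (w_max - w));
      y = y * std::exp(-(t - ty) / tau_minus) + 1.0; ty = t;
      ++j;
    } else {
      double t = pre[i];
      double y_t = y * std::exp(-(t - ty) / tau_minus);
      if (freeze) dw_sum += a_minus * y_t * w0;
      else w = clip(w + a_minus * y_t * w);
      x = x * std::exp(-(t - tx) / tau_plus) + 1.0; tx = t;
      ++i;
    }
  }
  return List::create(_["w"] = w, _["dw"] = freeze ? dw_sum : w - w0);
}
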