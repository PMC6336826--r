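#include <Rcpp.h>
using namespace Rcpp;

// Salient-event detection with a stochastic decaying threshold.
//
// Per timestep: compare the distance to the current threshold first; on a
// crossing (strict >) record an event and reset the threshold to T_max with
// D = 0, otherwise advance the threshold by
//   T <- T - ((T_max - T_min)/tau) * exp(-D/tau) + N(0, sd), D <- D + 1,
// where sd = (T_max - T_min)/alpha (or its square root when the noise
// parameter is read as a variance). In static mode the threshold is the
// constant T_max: no decay, no noise, resets are no-ops.
//
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List detect_core(NumericVector dist, double t_max, double t_min, double tau,
                 double alpha, bool noiseless, bool static_mode,
                 bool noise_as_variance, bool clamp_zero, bool keep_trace) {
  int n = dist.size();
  double range = t_max - t_min;
  double sd = noise_as_variance ? std::sqrt(range / alpha) : range / alpha;
  double T = t_max;
  double D = 0.0;
  std::vector<int> events;
  NumericVector trace(keep_trace ? n : 0);
  for (int t = 0; t < n; ++t) {
    if (keep_trace) trace[t] = T;
    if (dist[t] > T) {
      events.push_back(t + 1); // 1-based timestep index
      T = t_max;
      D = 0.0;
    } else if (!static_mode) {
      double noise = noiseless ? 0.0 : R::rnorm(0.0, sd);
      T += -(range / tau) * std::exp(-D / tau) + noise;
      D += 1.0;
      if (clamp_zero && T < 0.0) T = 0.0;
    }
  }
  return List::create(_["events"] = wrap(events), _["trace"] = trace,
                      _["final_threshold"] = T);
}
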