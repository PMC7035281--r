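#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov trace simulation with within-frame time averaging.
//
// The conformational path is sampled exactly (Gillespie) from the generator
// matrix Q (s^-1), then each camera frame of length `period` records the
// time-average of the state FRET means over the portion of the frame during
// which the fluorophore is emitting ("live"). Photobleaching truncates the
// live time permanently; blinking inserts transient dark intervals. All
// random draws use R's RNG so set.seed() governs reproducibility.
//
// Returns per-frame average FRET (over live time; 0 if frame fully dark),
// per-frame live fraction, the jump path, bleach time and blink intervals.
// [[Rcpp::export]]
List ctmc_trace_sim_cpp(NumericMatrix Q, NumericVector means, int start_state,
                        int n_frames, double period, double bleach_rate,
                        double blink_rate, double blink_recovery_rate) {
  const int ns = Q.nrow();
  const double T = n_frames * period;

  // exact jump path
  std::vector<double> jt;
  std::vector<int> js;
  double t = 0.0;
  int s = start_state - 1;
  jt.push_back(0.0);
  js.push_back(s);
  while (true) {
    double rate = -Q(s, s);
    if (rate <= 0.0) break;
    t += R::rexp(1.0 / rate);
    if (t >= T) break;
    double u = R::runif(0.0, rate);
    double acc = 0.0;
    int dest = -1;
    for (int j = 0; j < ns; ++j) {
      if (j == s) continue;
      acc += Q(s, j);
      if (u <= acc) { dest = j; break; }
    }
    if (dest < 0) {  // numeric slack: take the last state with positive rate
      for (int j = ns - 1; j >= 0; --j)
        if (j != s && Q(s, j) > 0.0) { dest = j; break; }
    }
    s = dest;
    jt.push_back(t);
    js.push_back(s);
  }

  // photophysics: exponential bleach time, alternating bright/dark blinks
  double bleach = (bleach_rate > 0.0) ? R::rexp(1.0 / bleach_rate) : R_PosInf;
  double horizon = std::min(bleach, T);
  std::vector<double> dstart, dend;
  if (blink_rate > 0.0 && blink_recovery_rate > 0.0) {
    double tb = 0.0;
    while (true) {
      tb += R::rexp(1.0 / blink_rate);
      if (tb >= horizon) break;
      double dur = R::rexp(1.0 / blink_recovery_rate);
      dstart.push_back(tb);
      dend.push_back(std::min(tb + dur, horizon));
      tb += dur;
      if (tb >= horizon) break;
    }
  }
  const size_t n_blinks = dstart.size();
  if (bleach < T) {  // bleached tail is one terminal dark interval
    dstart.push_back(bleach);
    dend.push_back(T);
  }

  NumericVector e_avg(n_frames), live_frac(n_frames);
  size_t pi = 0;  // index into jump path (segment jt[pi] .. jt[pi+1])
  size_t di0 = 0; // first dark interval possibly overlapping current time
  const size_t nseg = jt.size();
  const size_t nd = dstart.size();
  for (int f = 0; f < n_frames; ++f) {
    const double f0 = f * period, f1 = (f + 1) * period;
    while (pi + 1 < nseg && jt[pi + 1] <= f0) ++pi;
    while (di0 < nd && dend[di0] <= f0) ++di0;
    double live = 0.0, esum = 0.0;
    size_t p = pi;
    double a = f0;
    while (a < f1) {
      double b = f1;
      if (p + 1 < nseg && jt[p + 1] < b) b = jt[p + 1];
      // live time in [a, b): subtract dark overlap
      double seg = b - a;
      for (size_t d = di0; d < nd && dstart[d] < b; ++d) {
        double lo = std::max(a, dstart[d]);
        double hi = std::min(b, dend[d]);
        if (hi > lo) seg -= (hi - lo);
      }
      live += seg;
      esum += seg * means[js[p]];
      a = b;
      if (b >= f1) break;
      ++p;  // b < f1 implies b == jt[p + 1]: advance to the next segment
    }
    live_frac[f] = live / period;
    e_avg[f] = (live > 1e-12 * period) ? esum / live : 0.0;
  }

  return List::create(
    _["e_avg"] = e_avg, _["live_frac"] = live_frac,
    _["jump_times"] = wrap(jt),
    _["jump_states"] = IntegerVector(js.begin(), js.end()) + 1,
    _["bleach_time"] = bleach,
    _["blink_start"] = NumericVector(dstart.begin(), dstart.begin() + n_blinks),
    _["blink_end"] = NumericVector(dend.begin(), dend.begin() + n_blinks));
}
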