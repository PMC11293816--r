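#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Counter-based per-individual RNG substreams (splitmix64). Each individual's
// stream is a pure function of (seed, individual id), so simulated life
// courses do not depend on iteration order or on how work is chunked.
namespace {

inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t state;
  Stream(uint64_t seed, uint64_t id) {
    // decorrelate the (seed, id) lattice before use
    uint64_t s = seed;
    uint64_t a = splitmix64_next(s);
    s = a ^ (id * 0xD1B54A32D192ED03ULL + 0x8CB92BA72F3D8DD7ULL);
    state = splitmix64_next(s);
    (void)splitmix64_next(state);
  }
  // uniform on (0, 1); 53-bit resolution, never exactly 0 or 1
  double unif() {
    uint64_t x = splitmix64_next(state);
    double u = (double)(x >> 11) * (1.0 / 9007199254740992.0);
    if (u <= 0.0) u = 5e-324;
    return u;
  }
  double rexp1() { return -std::log(unif()); }
};

// Invert the cumulative hazard of a piecewise-constant hazard function.
// breaks has K+1 entries; haz[b] applies on [breaks[b], breaks[b+1]).
// Returns the age t > age at which the integrated hazard from `age` first
// reaches `target`, or +Inf if it never does before breaks[K] (censoring).
// If extend_last, the final band's hazard continues past breaks[K].
double invert_cum_hazard(const double *breaks, const double *haz, int K,
                         double age, double target, bool extend_last) {
  double acc = 0.0;
  for (int b = 0; b < K; ++b) {
    if (breaks[b + 1] <= age) continue;
    double lo = age > breaks[b] ? age : breaks[b];
    double add = haz[b] * (breaks[b + 1] - lo);
    if (acc + add >= target && haz[b] > 0.0)
      return lo + (target - acc) / haz[b];
    acc += add;
  }
  if (extend_last && haz[K - 1] > 0.0) {
    double lo = age > breaks[K] ? age : breaks[K];
    return lo + (target - acc) / haz[K - 1];
  }
  return R_PosInf;
}

} // namespace

// [[Rcpp::export]]
double cpp_invert_cum_hazard(NumericVector breaks, NumericVector hazards,
                             double age, double target) {
  return invert_cum_hazard(breaks.begin(), hazards.begin(),
                           (int)hazards.size(), age, target, false);
}

// Simulate one stratum's life courses on [breaks[0], breaks[K]].
// inc/rem: hazards per band; hist_inc/hist_rem (same length) replace them for
// all draws after an individual's first remission when use_history is true.
// [[Rcpp::export]]
List cpp_simulate_stratum(NumericVector breaks, NumericVector inc,
                          NumericVector rem, NumericVector hist_inc,
                          NumericVector hist_rem, bool use_history,
                          double prev_start, int n, double seed,
                          double id_offset) {
  int K = inc.size();
  double start = breaks[0], end = breaks[K];
  IntegerVector init(n);
  NumericVector onset(n, NA_REAL);
  NumericVector dur(n, 0.0);
  IntegerVector ntrans(n, 0);
  std::vector<int> t_id;
  std::vector<double> t_age;
  std::vector<int> t_state;

  const double *pb = breaks.begin();
  for (int i = 0; i < n; ++i) {
    Stream rng((uint64_t)seed, (uint64_t)(id_offset + i));
    int state = rng.unif() < prev_start ? 1 : 0;
    init[i] = state;
    bool remitted = false;
    double age = start;
    for (;;) {
      const double *h;
      if (state == 0)
        h = (use_history && remitted) ? hist_inc.begin() : inc.begin();
      else
        h = (use_history && remitted) ? hist_rem.begin() : rem.begin();
      double t = invert_cum_hazard(pb, h, K, age, rng.rexp1(), false);
      if (t >= end || !R_finite(t)) {
        if (state == 1) dur[i] += end - age;
        break;
      }
      if (state == 1) {
        dur[i] += t - age;
        remitted = true;
      } else if (ISNA(onset[i])) {
        onset[i] = t;
      }
      state = 1 - state;
      age = t;
      ++ntrans[i];
      t_id.push_back(i + 1);
      t_age.push_back(t);
      t_state.push_back(state);
    }
  }
  return List::create(
      _["initial_state"] = init, _["onset_age"] = onset,
      _["mdd_years"] = dur, _["n_transitions"] = ntrans,
      _["trans_id"] = IntegerVector(t_id.begin(), t_id.end()),
      _["trans_age"] = NumericVector(t_age.begin(), t_age.end()),
      _["trans_state"] = IntegerVector(t_state.begin(), t_state.end()));
}

// Exact interval outcome for heterogeneous individuals: starting in state0 at
// age0, run the two-state process with per-row band hazards for `gap` years
// and return the state at follow-up. The last band's hazards extend past the
// final break so that follow-ups beyond it remain defined.
// [[Rcpp::export]]
IntegerVector cpp_simulate_interval(NumericVector breaks, NumericMatrix inc,
                                    NumericMatrix rem, NumericVector age0,
                                    NumericVector gap, IntegerVector state0,
                                    double seed, double id_offset) {
  int n = age0.size(), K = inc.ncol();
  IntegerVector out(n);
  std::vector<double> hi(K), hr(K);
  const double *pb = breaks.begin();
  for (int i = 0; i < n; ++i) {
    for (int b = 0; b < K; ++b) {
      hi[b] = inc(i, b);
      hr[b] = rem(i, b);
    }
    Stream rng((uint64_t)seed, (uint64_t)(id_offset + i));
    int state = state0[i];
    double age = age0[i], stop = age0[i] + gap[i];
    for (;;) {
      const double *h = state == 0 ? hi.data() : hr.data();
      double t = invert_cum_hazard(pb, h, K, age, rng.rexp1(), true);
      if (t >= stop || !R_finite(t)) break;
      state = 1 - state;
      age = t;
    }
    out[i] = state;
  }
  return out;
}
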