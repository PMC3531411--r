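#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Self-contained, platform-stable RNG: mt19937_64 seeded through splitmix64,
// uniforms built from raw 64-bit words (std::*_distribution is
// implementation-defined and therefore avoided).
namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Mt64 {
  std::mt19937_64 eng;
  explicit Mt64(uint64_t seed) {
    uint64_t s = seed;
    eng.seed(splitmix64(s));
  }
  // uniform in (0, 1): 53-bit mantissa, zero excluded for safe log()
  double unif() {
    uint64_t x;
    do {
      x = eng() >> 11;
    } while (x == 0);
    return static_cast<double>(x) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

// child stream for replicate `rep` of master seed `seed`
inline uint64_t child_seed(uint64_t seed, uint64_t rep) {
  uint64_t s = seed ^ (0xD1B54A32D192ED03ULL * (rep + 1));
  return splitmix64(s);
}

struct StepResult {
  std::vector<double> n;       // current counts
  std::vector<int> d;          // divisions per type
  double consumed;
  double time;
  int n_events;
};

// One droplet realization. Overshoot rule: a division may fire whenever
// remaining resource > 0; it executes in full (resource may go negative).
// strict = division only allowed if it can be fully paid.
template <bool Record>
void run_one(const std::vector<double> &n0, const std::vector<double> &rates,
             const std::vector<double> &costs, double budget, bool gillespie,
             bool strict, Mt64 &rng, StepResult &out,
             std::vector<int> *events, std::vector<double> *times) {
  const int k = static_cast<int>(n0.size());
  out.n = n0;
  out.d.assign(k, 0);
  out.consumed = 0.0;
  out.time = 0.0;
  out.n_events = 0;
  double remaining = budget;

  for (;;) {
    if (remaining <= 0.0) break;
    double tot = 0.0;
    for (int i = 0; i < k; ++i) {
      if (strict && costs[i] > remaining + 1e-12) continue;
      tot += rates[i] * out.n[i];
    }
    if (tot <= 0.0) break;  // extinct or nothing affordable
    if (gillespie) out.time += rng.expo(tot);
    double u = rng.unif() * tot;
    int pick = -1;
    double acc = 0.0;
    for (int i = 0; i < k; ++i) {
      if (strict && costs[i] > remaining + 1e-12) continue;
      acc += rates[i] * out.n[i];
      if (u <= acc) { pick = i; break; }
    }
    if (pick < 0) pick = k - 1;
    out.n[pick] += 1.0;
    out.d[pick] += 1;
    out.consumed += costs[pick];
    remaining -= costs[pick];
    ++out.n_events;
    if (Record) {
      events->push_back(pick + 1);
      if (gillespie) times->push_back(out.time);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_one(NumericVector counts, NumericVector rates,
                      NumericVector costs, double budget, double seed,
                      bool gillespie, bool strict) {
  std::vector<double> n0(counts.begin(), counts.end());
  std::vector<double> rt(rates.begin(), rates.end());
  std::vector<double> cs(costs.begin(), costs.end());
  Mt64 rng(static_cast<uint64_t>(seed));
  StepResult res;
  std::vector<int> events;
  std::vector<double> times;
  run_one<true>(n0, rt, cs, budget, gillespie, strict, rng, res, &events,
                &times);
  List out = List::create(
      _["events"] = IntegerVector(events.begin(), events.end()),
      _["final_counts"] = NumericVector(res.n.begin(), res.n.end()),
      _["d_per_type"] = IntegerVector(res.d.begin(), res.d.end()),
      _["consumed"] = res.consumed, _["stopped"] = true,
      _["stop_time"] = gillespie ? res.time : NA_REAL);
  if (gillespie)
    out["times"] = NumericVector(times.begin(), times.end());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_ensemble(NumericVector counts, NumericVector rates,
                                    NumericVector costs, double budget,
                                    int n_reps, double seed, bool gillespie,
                                    bool strict) {
  const int k = counts.size();
  std::vector<double> n0(counts.begin(), counts.end());
  std::vector<double> rt(rates.begin(), rates.end());
  std::vector<double> cs(costs.begin(), costs.end());
  NumericMatrix out(n_reps, k + 3);  // d_1..d_k, n_final, consumed, stop_time
  StepResult res;
  for (int r = 0; r < n_reps; ++r) {
    Mt64 rng(child_seed(static_cast<uint64_t>(seed), r));
    run_one<false>(n0, rt, cs, budget, gillespie, strict, rng, res, nullptr,
                   nullptr);
    double nf = 0.0;
    for (int i = 0; i < k; ++i) {
      out(r, i) = res.d[i];
      nf += res.n[i];
    }
    out(r, k) = nf;
    out(r, k + 1) = res.consumed;
    out(r, k + 2) = gillespie ? res.time : NA_REAL;
  }
  return out;
}

// Generalized Polya urn: type i starts with k_i * a_i balls; a drawn ball of
// color i is returned with k_i extra balls of its color. Returns draw counts
// of color 1 after D draws, one per replicate.
// [[Rcpp::export]]
IntegerVector cpp_urn_draws(int a1, int a2, int k1, int k2, int D, int n_reps,
                            double seed) {
  IntegerVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    Mt64 rng(child_seed(static_cast<uint64_t>(seed) ^ 0xA5A5A5A5ULL, r));
    double b1 = static_cast<double>(k1) * a1;
    double b2 = static_cast<double>(k2) * a2;
    int d1 = 0;
    for (int t = 0; t < D; ++t) {
      if (rng.unif() * (b1 + b2) <= b1) {
        b1 += k1;
        ++d1;
      } else {
        b2 += k2;
      }
    }
    out[r] = d1;
  }
  return out;
}
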