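#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Per-woman counter-based RNG: splitmix64 streams keyed by (root seed, woman
// index). Histories are therefore independent of execution order, so a
// parallel driver would reproduce the sequential results bit for bit.
static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t& state) {
  // 53-bit mantissa in [0, 1)
  return (double)(splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t woman_stream(int seed, int w) {
  uint64_t s = ((uint64_t)(uint32_t)seed << 32) ^
               (0x9E3779B97F4A7C15ULL * (uint64_t)(w + 1));
  splitmix64(s);
  splitmix64(s);
  return s;
}

// Simulate one cohort of women from marriage to the end of the reproductive
// window (month `horizon`, exclusive). Within a month: expire pregnancy /
// amenorrhea first, then at most one Bernoulli conception trial with
// probability min(1, z * phi[month]). A conception at month c gives a birth
// at c + gestation (recorded only if it falls before `horizon`) and blocks
// further trials through month c + gestation + nonsusc; the next trial is at
// c + gestation + nonsusc + 1. Pregnancies whose birth would fall at or
// after `horizon` are censored: neither conception nor birth is recorded.
//
// marriage_months: real-valued marriage ages in months; first trial is the
// first whole month strictly after marriage.
// phi_by_month[m]: monthly conception probability at age m months (0 outside
// the fecund window).
//
// Returns per-age birth counts (completed age = floor(birth_month / 12)) and,
// if keep_histories, the vector of recorded conception months per woman.
// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(NumericVector marriage_months,
                    NumericVector frailty,
                    NumericVector phi_by_month,
                    int gestation,
                    int nonsusc,
                    int horizon,
                    int seed,
                    bool keep_histories) {
  const int n = marriage_months.size();
  const int n_phi = phi_by_month.size();
  const int n_ages = horizon / 12 + 1;
  IntegerVector counts(n_ages);
  List hist(keep_histories ? n : 0);
  std::vector<int> conc;

  for (int w = 0; w < n; ++w) {
    uint64_t state = woman_stream(seed, w);
    conc.clear();
    const double z = frailty[w];
    int t = (int)std::floor(marriage_months[w]) + 1;
    if (t < 0) t = 0;
    while (t < horizon) {
      double p = (t < n_phi) ? phi_by_month[t] : 0.0;
      if (p > 0.0) {
        p *= z;
        if (p > 1.0) p = 1.0;
        if (unif01(state) < p) {
          const int birth = t + gestation;
          if (birth < horizon) {
            conc.push_back(t);
            counts[birth / 12] += 1;
          }
          t = birth + nonsusc + 1;
          continue;
        }
      }
      ++t;
    }
    if (keep_histories) hist[w] = IntegerVector(conc.begin(), conc.end());
  }

  return List::create(_["counts"] = counts, _["conceptions"] = hist);
}
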