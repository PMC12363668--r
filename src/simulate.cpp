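// Monte-Carlo engine for bd / db updating on a fixed graph.
//
// Each replicate runs on its own counter-based random stream: the user seed
// and the replicate index are mixed through splitmix64 to seed a private
// xoshiro256++ generator, so replicates are reproducible independently of
// execution order and of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro256pp(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform integer in [0, n) by 128-bit multiply (Lemire); bias-free enough
  // at n <= 2^31 for any conceivable run length
  int unif_int(uint32_t n) {
    return (int)(((__uint128_t)next() * n) >> 64);
  }
};

struct FlatAdj {
  std::vector<int> nbr;     // concatenated neighbor lists (0-based)
  std::vector<int> offset;  // offset[v] .. offset[v+1]-1
  int n;

  FlatAdj(const Rcpp::List &adj) {
    n = adj.size();
    offset.resize(n + 1);
    offset[0] = 0;
    for (int v = 0; v < n; ++v) {
      Rcpp::IntegerVector nb = adj[v];
      offset[v + 1] = offset[v] + nb.size();
    }
    nbr.resize(offset[n]);
    for (int v = 0; v < n; ++v) {
      Rcpp::IntegerVector nb = adj[v];
      for (int k = 0; k < nb.size(); ++k) nbr[offset[v] + k] = nb[k] - 1;
    }
  }
};

// One replicate. adj holds out-neighbors for bd, in-neighbors for db.
// Under bd the first draw is the birth vertex and the copy runs first->second;
// under db the first draw is the death vertex and the copy runs second->first.
struct RunResult {
  double time;
  int winner;      // 0-based winning type, -1 if censored
  bool censored;
};

RunResult run_one(const FlatAdj &adj, bool bd, std::vector<int> &x,
                  double max_steps, Xoshiro256pp &rng,
                  const std::vector<double> *record_at = nullptr,
                  std::vector<int> *diversity_out = nullptr) {
  const int n = adj.n;
  std::vector<int> count(n, 0);
  int distinct = 0;
  for (int i = 0; i < n; ++i) {
    if (count[x[i]]++ == 0) ++distinct;
  }
  double t = 0.0;
  size_t rec_idx = 0;
  const size_t n_rec = record_at ? record_at->size() : 0;

  auto flush_records = [&](double now) {
    while (rec_idx < n_rec && (*record_at)[rec_idx] <= now) {
      (*diversity_out)[rec_idx] = distinct;
      ++rec_idx;
    }
  };

  if (record_at) flush_records(0.0);

  while (distinct > 1 && t < max_steps) {
    int first = rng.unif_int((uint32_t)n);
    int off = adj.offset[first];
    int deg = adj.offset[first + 1] - off;
    int second = adj.nbr[off + rng.unif_int((uint32_t)deg)];
    int src = bd ? first : second;
    int dst = bd ? second : first;
    t += 1.0;
    if (x[dst] != x[src]) {
      if (--count[x[dst]] == 0) --distinct;
      x[dst] = x[src];
      ++count[x[dst]];
    }
    if (record_at) flush_records(t);
  }
  if (record_at) {
    // configuration is frozen after absorption (or censoring)
    while (rec_idx < n_rec) (*diversity_out)[rec_idx++] = distinct;
  }
  RunResult out;
  out.censored = distinct > 1;
  out.time = t;
  out.winner = out.censored ? -1 : x[0];
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate_batch")]]
Rcpp::List cpp_simulate_batch(Rcpp::List adj, bool bd, Rcpp::IntegerVector x0,
                              int reps, double seed, double max_steps) {
  FlatAdj fa(adj);
  Rcpp::NumericVector times(reps);
  Rcpp::IntegerVector winners(reps);
  Rcpp::LogicalVector censored(reps);
  std::vector<int> x(fa.n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < fa.n; ++i) x[i] = x0[i] - 1;
    Xoshiro256pp rng((uint64_t)seed, (uint64_t)(r + 1));
    RunResult res = run_one(fa, bd, x, max_steps, rng);
    times[r] = res.time;
    winners[r] = res.censored ? NA_INTEGER : res.winner + 1;
    censored[r] = res.censored;
    if ((r & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("winners") = winners,
                            Rcpp::Named("censored") = censored);
}

// [[Rcpp::export(name = ".cpp_diversity_curve")]]
Rcpp::NumericVector cpp_diversity_curve(Rcpp::List adj, bool bd,
                                        Rcpp::IntegerVector x0, int reps,
                                        double seed,
                                        Rcpp::NumericVector time_points,
                                        double max_steps) {
  FlatAdj fa(adj);
  std::vector<double> rec(time_points.begin(), time_points.end());
  std::vector<int> div(rec.size());
  Rcpp::NumericVector acc(rec.size());
  std::vector<int> x(fa.n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < fa.n; ++i) x[i] = x0[i] - 1;
    Xoshiro256pp rng((uint64_t)seed, (uint64_t)(r + 1));
    run_one(fa, bd, x, max_steps, rng, &rec, &div);
    for (size_t k = 0; k < rec.size(); ++k) acc[k] += div[k];
    if ((r & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  for (size_t k = 0; k < rec.size(); ++k) acc[k] /= reps;
  return acc;
}
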