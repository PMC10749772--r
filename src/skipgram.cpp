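#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64 seeded xorshift-style generator: deterministic across platforms
// (std::mt19937 ordering of operations would also work, but a hand-rolled
// generator keeps the bit stream independent of the standard library build).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0 / (1.0 + std::exp(-8.0));
  if (x < -8.0) return 1.0 / (1.0 + std::exp(8.0));
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer token streams.
// sentences: list of 0-based integer vectors (tokens; negatives excluded
// upstream). Returns the V x dim input-vector matrix.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, int dim,
                         int window, int negative, int epochs,
                         double alpha0, double alpha_min, int seed) {
  Rng rng(static_cast<uint64_t>(seed));

  // unigram counts -> negative-sampling table (power 0.75)
  std::vector<double> counts(vocab_size, 0.0);
  long long n_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sent = sentences[s];
    for (int t = 0; t < sent.size(); ++t) { counts[sent[t]] += 1.0; ++n_tokens; }
  }
  if (n_tokens == 0) stop("empty corpus");
  const int table_size = 100000;
  std::vector<int> neg_table(table_size);
  {
    double total = 0.0;
    for (int v = 0; v < vocab_size; ++v) total += std::pow(counts[v], 0.75);
    double cum = std::pow(counts[0], 0.75) / total;
    int v = 0;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = v;
      if ((i + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const long long total_steps = static_cast<long long>(epochs) * n_tokens;
  long long step = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int t = 0; t < n; ++t, ++step) {
        double alpha = alpha0 * (1.0 - static_cast<double>(step) / total_steps);
        if (alpha < alpha_min) alpha = alpha_min;
        const int b = rng.below(window) + 1;  // dynamic window, word2vec-style
        const int center = sent[t];
        double* v_c = &syn0[static_cast<size_t>(center) * dim];
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          const int pos = t + off;
          if (pos < 0 || pos >= n) continue;
          const int ctx = sent[pos];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = ctx; label = 1.0; }
            else {
              target = neg_table[rng.below(table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_t = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += v_c[j] * v_t[j];
            const double g = (label - sigmoid_clip(dot)) * alpha;
            for (int j = 0; j < dim; ++j) {
              grad[j] += g * v_t[j];
              v_t[j] += g * v_c[j];
            }
          }
          for (int j = 0; j < dim; ++j) v_c[j] += grad[j];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int j = 0; j < dim; ++j)
      out(v, j) = syn0[static_cast<size_t>(v) * dim + j];
  return out;
}
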