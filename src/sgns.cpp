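#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic xorshift64* stream so training never touches R's RNG and two
// runs with the same seed are bit-identical.
static inline uint64_t next_rand(uint64_t& s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}
static inline double unif01(uint64_t& s) {
  return (next_rand(s) >> 11) * (1.0 / 9007199254740992.0);  // 53-bit mantissa
}
static inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling. `sentences` holds 0-based vocabulary
// indices (out-of-vocabulary tokens already removed). `noise_cdf` is the
// cumulative unigram^0.75 distribution used to draw negative samples.
// Returns the input-embedding matrix, vocab_size x dim.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size, NumericVector noise_cdf,
                             int dim, int window, int negative, int iterations,
                             double alpha, double min_alpha, double seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  uint64_t rng = static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL;
  next_rand(rng);

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  const int n_sent = sentences.size();
  double total_words = 0.0;
  for (int s = 0; s < n_sent; ++s)
    total_words += as<IntegerVector>(sentences[s]).size();
  const double total_steps = std::max(1.0, total_words * iterations);

  std::vector<double> grad(dim);
  double processed = 0.0;
  const int ncdf = noise_cdf.size();

  for (int it = 0; it < iterations; ++it) {
    for (int s = 0; s < n_sent; ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        const int center = sent[pos];
        const double lr = std::max(min_alpha, alpha * (1.0 - processed / total_steps));
        processed += 1.0;
        // dynamic window as in the reference implementation
        const int reduced = static_cast<int>(next_rand(rng) % static_cast<uint64_t>(window));
        const int cw = window - reduced;
        for (int off = -cw; off <= cw; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int context = sent[cpos];
          double* l1 = &syn0[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              const double u = unif01(rng);
              int lo = 0, hi = ncdf - 1;
              while (lo < hi) {  // first index with cdf >= u
                const int mid = (lo + hi) / 2;
                if (noise_cdf[mid] < u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == center) continue;
              label = 0.0;
            }
            double* l2 = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += l1[k] * l2[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * l2[k];
              l2[k] += g * l1[k];
            }
          }
          for (int k = 0; k < dim; ++k) l1[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}
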