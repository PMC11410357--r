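#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic 64-bit xorshift so training is reproducible across platforms
// independently of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double unif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling on pre-indexed sentences.
// sentences: list of integer vectors, 0-based vocabulary indices.
// counts: vocabulary frequencies (for the unigram^0.75 negative table).
// Window is symmetric and fixed (N tokens each side). Single-threaded and
// fully deterministic given `seed`.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector counts, int dim,
                         int window, int negative, int epochs,
                         double lr0, int seed) {
  const int V = counts.size();
  uint64_t rng = (uint64_t)seed * 2862933555777941757ULL + 3037000493ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int v = 0; v < V; ++v) {
    tot += std::pow((double)counts[v], 0.75);
    cum[v] = tot;
  }

  // total center-context pairs for the linear learning-rate schedule
  long long total_pairs = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sen = sentences[s];
    int n = sen.size();
    for (int i = 0; i < n; ++i) {
      int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);
      total_pairs += hi - lo;
    }
  }
  total_pairs *= epochs;
  if (total_pairs < 1) total_pairs = 1;

  std::vector<double> grad(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sen = sentences[s];
      int n = sen.size();
      for (int i = 0; i < n; ++i) {
        int center = sen[i];
        int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          double lr = lr0 * (1.0 - (double)done / total_pairs);
          if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
          ++done;
          int context = sen[j];
          double *v0 = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = context;
              label = 1.0;
            } else {
              double r = unif01(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                             cum.begin());
              if (target >= V) target = V - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
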