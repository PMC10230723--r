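// Distributed-memory (PV-DM) paragraph-vector training with negative
// sampling.  Single-threaded with a self-contained RNG so that a fixed seed
// reproduces the trained vectors bit for bit.
//
// The model predicts each center word from the mean of its context-word
// input vectors plus the document vector; parameters are updated by SGD on
// the negative-sampling objective with a linearly decaying learning rate.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift64* generator: fast, portable, deterministic across platforms.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return static_cast<int>(unif() * n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".s2v_train_cpp")]]
List s2v_train_cpp(List docs, int vocab_size, NumericVector word_counts,
                   int dim, int window, int epochs, int negative,
                   double alpha, double min_alpha, uint64_t seed) {
  const int V = vocab_size;
  const int D = dim;
  const int n_docs = docs.size();

  // Pre-extract documents as raw int pointers (0-based ids).
  std::vector<std::vector<int>> dv(n_docs);
  long long total_words = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector w = docs[d];
    dv[d].assign(w.begin(), w.end());
    total_words += dv[d].size();
  }

  Rng rng(seed);

  // Input vectors (words and documents) start small and random; the output
  // (context) matrix starts at zero, as in the reference word2vec scheme.
  std::vector<double> syn0(static_cast<size_t>(V) * D);
  std::vector<double> dvec(static_cast<size_t>(n_docs) * D);
  std::vector<double> syn1(static_cast<size_t>(V) * D, 0.0);
  for (auto &x : syn0) x = (rng.unif() - 0.5) / D;
  for (auto &x : dvec) x = (rng.unif() - 0.5) / D;

  // Unigram table with the conventional 0.75 power for negative sampling.
  const int table_size = std::max(V * 8, 1 << 16);
  std::vector<int> unigram(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < V; ++i) z += std::pow(word_counts[i], 0.75);
    double cum = std::pow(word_counts[0], 0.75) / z;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      unigram[i] = w;
      if (static_cast<double>(i + 1) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow(word_counts[w], 0.75) / z;
      }
    }
  }

  std::vector<double> hid(D), err(D);
  const long long sched_total = static_cast<long long>(epochs) * total_words;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int> &doc = dv[d];
      const int n = static_cast<int>(doc.size());
      double *dp = &dvec[static_cast<size_t>(d) * D];
      for (int t = 0; t < n; ++t) {
        double lr = alpha;
        if (sched_total > 1) {
          lr = alpha - (alpha - min_alpha) *
              (static_cast<double>(processed) / (sched_total - 1));
        }
        ++processed;

        const int center = doc[t];
        const int lo = std::max(0, t - window);
        const int hi = std::min(n - 1, t + window);

        // hidden = mean of context-word vectors and the document vector
        int cnt = 1;
        for (int j = 0; j < D; ++j) hid[j] = dp[j];
        for (int p = lo; p <= hi; ++p) {
          if (p == t) continue;
          const double *wv = &syn0[static_cast<size_t>(doc[p]) * D];
          for (int j = 0; j < D; ++j) hid[j] += wv[j];
          ++cnt;
        }
        for (int j = 0; j < D; ++j) hid[j] /= cnt;

        std::fill(err.begin(), err.end(), 0.0);
        for (int s = 0; s <= negative; ++s) {
          int target;
          double label;
          if (s == 0) {
            target = center;
            label = 1.0;
          } else {
            target = unigram[rng.below(table_size)];
            if (target == center) continue;
            label = 0.0;
          }
          double *ov = &syn1[static_cast<size_t>(target) * D];
          double f = 0.0;
          for (int j = 0; j < D; ++j) f += hid[j] * ov[j];
          const double g = (label - sigmoid(f)) * lr;
          for (int j = 0; j < D; ++j) err[j] += g * ov[j];
          for (int j = 0; j < D; ++j) ov[j] += g * hid[j];
        }

        // propagate the accumulated error to every contributor
        for (int j = 0; j < D; ++j) dp[j] += err[j];
        for (int p = lo; p <= hi; ++p) {
          if (p == t) continue;
          double *wv = &syn0[static_cast<size_t>(doc[p]) * D];
          for (int j = 0; j < D; ++j) wv[j] += err[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix wout(V, D), dout(n_docs, D);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < D; ++j) wout(i, j) = syn0[static_cast<size_t>(i) * D + j];
  for (int i = 0; i < n_docs; ++i)
    for (int j = 0; j < D; ++j) dout(i, j) = dvec[static_cast<size_t>(i) * D + j];
  return List::create(_["word_vectors"] = wout, _["doc_vectors"] = dout);
}
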