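// word2vec-style embedding trainer: skip-gram / CBOW with negative sampling.
// Single-threaded with an internal xorshift RNG so that a fixed seed gives
// bit-identical vectors across runs and platforms.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List sentences, NumericVector vocab_counts,
                             int dim, int window, int negative, int epochs,
                             double alpha0, int seed, bool cbow) {
  const int V = vocab_counts.size();
  if (V == 0) stop("empty vocabulary");

  // negative-sampling table, unigram distribution to the 3/4 power
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    std::vector<double> pw(V);
    for (int i = 0; i < V; ++i) { pw[i] = std::pow(vocab_counts[i], 0.75); total += pw[i]; }
    int i = 0;
    double cum = pw[0] / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((t + 1.0) / table_size > cum && i < V - 1) {
        ++i;
        cum += pw[i] / total;
      }
    }
  }

  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // copy sentences into flat int vectors
  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector iv = sentences[s];
    std::vector<int> v(iv.begin(), iv.end());
    total_words += v.size();
    sents.push_back(std::move(v));
  }
  if (total_words == 0) stop("no trainable tokens");

  const double alpha_min = alpha0 * 1e-4;
  const long long train_total = total_words * static_cast<long long>(epochs);
  long long processed = 0;
  std::vector<double> neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sen = sents[s];
      const int slen = static_cast<int>(sen.size());
      for (int pos = 0; pos < slen; ++pos) {
        ++processed;
        double alpha = alpha0 * (1.0 - static_cast<double>(processed) / (train_total + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        const int word = sen[pos];
        // dynamic window shrink, as in the reference implementation
        const int b = static_cast<int>(rng.below(static_cast<uint64_t>(window)));
        const int lo = std::max(0, pos - window + b);
        const int hi = std::min(slen - 1, pos + window - b);

        if (!cbow) {
          // skip-gram: each context word predicts the center word
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            const int ctx = sen[c];
            double* v_in = &syn0[static_cast<size_t>(ctx) * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int d = 0; d < negative + 1; ++d) {
              int target; double label;
              if (d == 0) { target = word; label = 1.0; }
              else {
                target = table[rng.below(table_size)];
                if (target == word) continue;
                label = 0.0;
              }
              double* v_out = &syn1[static_cast<size_t>(target) * dim];
              double f = 0.0;
              for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
              const double g = (label - sigmoid(f)) * alpha;
              for (int k = 0; k < dim; ++k) neu1e[k] += g * v_out[k];
              for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
            }
            for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
          }
        } else {
          // CBOW: averaged context predicts the center word
          int cw = 0;
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            double* v_in = &syn0[static_cast<size_t>(sen[c]) * dim];
            for (int k = 0; k < dim; ++k) neu1[k] += v_in[k];
            ++cw;
          }
          if (cw == 0) continue;
          for (int k = 0; k < dim; ++k) neu1[k] /= cw;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target; double label;
            if (d == 0) { target = word; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == word) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += neu1[k] * v_out[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * neu1[k];
          }
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            double* v_in = &syn0[static_cast<size_t>(sen[c]) * dim];
            for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}
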