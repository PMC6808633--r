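// Single-threaded word2vec-style trainer with negative sampling.
// Supports skip-gram, CBOW and a fastText-like subword mode in which the
// input representation of a word is the mean of its own vector and the
// vectors of its hashed character n-gram buckets.  Single worker + own
// xorshift RNG => bitwise-reproducible for a fixed seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 0x2545F4914F6CDD1DULL;
}

static inline double runif01(uint64_t &s) {
  return (double)(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid_clipped(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List sgns_train_cpp(List sentences, int vocab_size, NumericVector counts,
                    int dim, int window, int negative, int epochs,
                    double alpha0, bool cbow, List subword, int n_buckets,
                    double seed) {
  const bool use_sub = n_buckets > 0;

  std::vector< std::vector<int> > sents(sentences.size());
  long long corpus_words = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector v = sentences[i];
    sents[i].assign(v.begin(), v.end());
    corpus_words += v.size();
  }

  std::vector< std::vector<int> > sub(vocab_size);
  if (use_sub) {
    for (int i = 0; i < vocab_size; ++i) {
      IntegerVector v = subword[i];
      sub[i].assign(v.begin(), v.end());
    }
  }

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }

  uint64_t rs = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
  if (rs == 0) rs = 1;

  std::vector<double> Win((size_t)vocab_size * dim);
  std::vector<double> Bin(use_sub ? (size_t)n_buckets * dim : 0);
  std::vector<double> Wout((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < Win.size(); ++i) Win[i] = (runif01(rs) - 0.5) / dim;
  for (size_t i = 0; i < Bin.size(); ++i) Bin[i] = (runif01(rs) - 0.5) / dim;

  const long long total = std::max(1LL, (long long)epochs * corpus_words);
  long long processed = 0;

  std::vector<double> h(dim), gerr(dim);
  std::vector<double*> comps;
  comps.reserve(64);

  // append the composition rows (word row + its subword bucket rows)
  auto push_components = [&](int w) {
    comps.push_back(&Win[(size_t)w * dim]);
    if (use_sub)
      for (size_t j = 0; j < sub[w].size(); ++j)
        comps.push_back(&Bin[(size_t)sub[w][j] * dim]);
  };

  auto sample_negative = [&]() -> int {
    double r = runif01(rs) * tot;
    return (int)(std::upper_bound(cum.begin(), cum.end(), r) - cum.begin());
  };

  // one (input composition -> output word) update with `negative` negatives
  auto train_pair = [&](int target_word, double alpha) {
    const size_t nc = comps.size();
    const double inv = 1.0 / (double)nc;
    for (int k = 0; k < dim; ++k) {
      double s = 0.0;
      for (size_t j = 0; j < nc; ++j) s += comps[j][k];
      h[k] = s * inv;
      gerr[k] = 0.0;
    }
    for (int d = 0; d <= negative; ++d) {
      int target;
      double label;
      if (d == 0) {
        target = target_word;
        label = 1.0;
      } else {
        target = sample_negative();
        if (target == target_word) continue;
        label = 0.0;
      }
      double *out = &Wout[(size_t)target * dim];
      double f = 0.0;
      for (int k = 0; k < dim; ++k) f += h[k] * out[k];
      double g = (label - sigmoid_clipped(f)) * alpha;
      for (int k = 0; k < dim; ++k) {
        gerr[k] += g * out[k];
        out[k] += g * h[k];
      }
    }
    for (size_t j = 0; j < nc; ++j)
      for (int k = 0; k < dim; ++k)
        comps[j][k] += gerr[k] * inv;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < sents.size(); ++si) {
      const std::vector<int> &sen = sents[si];
      const int n = (int)sen.size();
      for (int t = 0; t < n; ++t) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)total);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        ++processed;
        // reduced dynamic window, as in the reference implementation
        int b = (int)(xorshift64(rs) % (uint64_t)window);
        int lo = std::max(0, t - window + b);
        int hi = std::min(n - 1, t + window - b);
        if (cbow) {
          comps.clear();
          for (int j = lo; j <= hi; ++j)
            if (j != t) push_components(sen[j]);
          if (!comps.empty()) train_pair(sen[t], alpha);
        } else {
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            comps.clear();
            push_components(sen[t]);
            train_pair(sen[j], alpha);
          }
        }
      }
    }
  }

  NumericMatrix wm(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      wm(i, k) = Win[(size_t)i * dim + k];
  NumericMatrix bm(use_sub ? n_buckets : 0, dim);
  if (use_sub)
    for (int i = 0; i < n_buckets; ++i)
      for (int k = 0; k < dim; ++k)
        bm(i, k) = Bin[(size_t)i * dim + k];

  return List::create(_["words"] = wm, _["buckets"] = bm);
}
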