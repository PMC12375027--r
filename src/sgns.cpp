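#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// xorshift64* PRNG: single-threaded, fully determined by the seed so the
// walk-based embeddings are bit-reproducible across platforms.
static inline uint64_t next_state(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double next_unif(uint64_t &s) {
  return (next_state(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over pre-generated random walks.
// walks: list of integer vectors (0-based node indices); neg_cdf:
// cumulative unigram^0.75 sampling distribution over nodes.
// [[Rcpp::export]]
NumericMatrix train_sgns_cpp(List walks, int n_nodes, int dim, int window,
                             int negative, int epochs, double alpha,
                             NumericVector neg_cdf, int seed) {
  uint64_t state = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  next_state(state);

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (next_unif(state) - 0.5) / dim;

  std::vector<double> grad(dim);
  int n_walks = walks.size();
  const double *cdf = neg_cdf.begin();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      IntegerVector walk = walks[w];
      int len = walk.size();
      for (int i = 0; i < len; ++i) {
        int center = walk[i];
        int lo = i - window < 0 ? 0 : i - window;
        int hi = i + window >= len ? len - 1 : i + window;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int context = walk[j];
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = next_unif(state);
              target = (int)(std::lower_bound(cdf, cdf + n_nodes, u) - cdf);
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
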