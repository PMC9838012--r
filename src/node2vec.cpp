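#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Random-walk node embedding: uniform (p = q = 1) walks over an undirected
// graph followed by skip-gram training with negative sampling. Single
// threaded and fully determined by `seed`. Isolated nodes receive all-zero
// embeddings.
//
// `adj` is a list of 1-based integer neighbour vectors, one per node.
// [[Rcpp::export]]
NumericMatrix node2vec_embed_cpp(List adj, int dim, int walk_length,
                                 int walks_per_node, int window, int negative,
                                 int epochs, double lr, int seed) {
  const int n = adj.size();
  std::vector<std::vector<int>> nbr(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector a = adj[v];
    nbr[v].reserve(a.size());
    for (int x : a) nbr[v].push_back(x - 1);
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));

  // Uniform random walks from every non-isolated node.
  std::vector<std::vector<int>> walks;
  walks.reserve(static_cast<size_t>(n) * walks_per_node);
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int v = 0; v < n; ++v) {
      if (nbr[v].empty()) continue;
      std::vector<int> w;
      w.reserve(walk_length);
      w.push_back(v);
      int cur = v;
      for (int s = 1; s < walk_length; ++s) {
        const std::vector<int>& nb = nbr[cur];
        if (nb.empty()) break;
        std::uniform_int_distribution<int> pick(0, static_cast<int>(nb.size()) - 1);
        cur = nb[pick(rng)];
        w.push_back(cur);
      }
      walks.push_back(std::move(w));
    }
  }

  // Unigram^0.75 table for negative sampling.
  std::vector<double> cnt(n, 0.0), cum(n, 0.0);
  for (const auto& w : walks)
    for (int v : w) cnt[v] += 1.0;
  double tot = 0.0;
  for (int v = 0; v < n; ++v) {
    tot += std::pow(cnt[v], 0.75);
    cum[v] = tot;
  }

  std::vector<double> W(static_cast<size_t>(n) * dim);
  std::vector<double> C(static_cast<size_t>(n) * dim, 0.0);
  std::uniform_real_distribution<double> uinit(-0.5, 0.5);
  for (auto& x : W) x = uinit(rng) / dim;

  std::uniform_real_distribution<double> u01(0.0, 1.0);
  std::uniform_int_distribution<int> rwin(1, window);
  std::vector<double> gcenter(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& w : walks) {
      const int len = static_cast<int>(w.size());
      for (int c = 0; c < len; ++c) {
        const int b = rwin(rng);  // shrunken window, as in word2vec
        const int lo = std::max(0, c - b), hi = std::min(len - 1, c + b);
        const int center = w[c];
        for (int t = lo; t <= hi; ++t) {
          if (t == c) continue;
          std::fill(gcenter.begin(), gcenter.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int tgt;
            double label;
            if (k == 0) {
              tgt = w[t];
              label = 1.0;
            } else {
              const double r = u01(rng) * tot;
              tgt = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), r) -
                                     cum.begin());
              if (tgt == center) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int d = 0; d < dim; ++d)
              dot += W[static_cast<size_t>(center) * dim + d] *
                     C[static_cast<size_t>(tgt) * dim + d];
            const double p = 1.0 / (1.0 + std::exp(-dot));
            const double g = lr * (label - p);
            for (int d = 0; d < dim; ++d) {
              gcenter[d] += g * C[static_cast<size_t>(tgt) * dim + d];
              C[static_cast<size_t>(tgt) * dim + d] +=
                  g * W[static_cast<size_t>(center) * dim + d];
            }
          }
          for (int d = 0; d < dim; ++d)
            W[static_cast<size_t>(center) * dim + d] += gcenter[d];
        }
      }
    }
  }

  NumericMatrix out(n, dim);
  for (int v = 0; v < n; ++v) {
    if (nbr[v].empty()) continue;  // isolated: stays zero
    for (int d = 0; d < dim; ++d)
      out(v, d) = W[static_cast<size_t>(v) * dim + d];
  }
  return out;
}
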