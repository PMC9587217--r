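// Degree-matched directed surrogate networks by double-edge swaps.
// Swap (a->b, c->d) => (a->d, c->b), rejected if it would create a self-loop
// or a multi-edge. Edge weights travel with the source (out-going) endpoint.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List mm_edge_swap_cpp(IntegerVector from, IntegerVector to, NumericVector w,
                      int n_nodes, int n_surrogates, int n_passes, int seed) {
  const int ne = from.size();
  List out(n_surrogates);
  if (ne < 2) {
    for (int s = 0; s < n_surrogates; ++s)
      out[s] = List::create(_["from"] = from, _["to"] = to, _["weight"] = w);
    return out;
  }

  for (int s = 0; s < n_surrogates; ++s) {
    std::mt19937 rng((unsigned)seed + 0x85ebca6bu * (unsigned)(s + 1));
    std::uniform_int_distribution<int> pick(0, ne - 1);

    std::vector<int> f(from.begin(), from.end());
    std::vector<int> t(to.begin(), to.end());
    std::vector<double> ww(w.begin(), w.end());
    std::unordered_set<long long> edges;
    edges.reserve(ne * 2);
    for (int e = 0; e < ne; ++e)
      edges.insert((long long)f[e] * n_nodes + t[e]);

    long long attempts = (long long)n_passes * ne;
    for (long long a = 0; a < attempts; ++a) {
      int e1 = pick(rng), e2 = pick(rng);
      if (e1 == e2) continue;
      int A = f[e1], B = t[e1], C = f[e2], D = t[e2];
      if (A == D || C == B) continue;                  // would create self-loop
      long long k1 = (long long)A * n_nodes + D;
      long long k2 = (long long)C * n_nodes + B;
      if (edges.count(k1) || edges.count(k2)) continue;  // multi-edge
      edges.erase((long long)A * n_nodes + B);
      edges.erase((long long)C * n_nodes + D);
      edges.insert(k1);
      edges.insert(k2);
      t[e1] = D;  // weight ww[e1] stays with source A
      t[e2] = B;  // weight ww[e2] stays with source C
    }

    out[s] = List::create(_["from"] = IntegerVector(f.begin(), f.end()),
                          _["to"] = IntegerVector(t.begin(), t.end()),
                          _["weight"] = NumericVector(ww.begin(), ww.end()));
  }
  return out;
}
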