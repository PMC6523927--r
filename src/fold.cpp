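#include <Rcpp.h>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum
// hairpin-loop size and no pseudoknots.  bases: 0=A,1=C,2=G,3=T.
// wt: 4x4 pair-weight matrix (0 = not pairable).
// Deterministic traceback: at (i,j) a pairing of j is preferred over
// leaving j unpaired on ties, and among tied partners the leftmost
// (smallest k) is taken.
// [[Rcpp::export]]
List fold_nussinov_cpp(IntegerVector bases, int min_loop,
                       IntegerMatrix wt) {
  const int n = bases.size();
  IntegerVector pairs(n, 0);
  if (n == 0) return List::create(_["pairs"] = pairs, _["score"] = 0);

  std::vector<int> M((size_t)n * n, 0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[idx(i, j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = wt(bases[k], bases[j]);
        if (w == 0) continue;
        int left = (k > i) ? M[idx(i, k - 1)] : 0;
        int inner = (k + 1 <= j - 1) ? M[idx(k + 1, j - 1)] : 0;
        int cand = left + w + inner;
        if (cand > best) best = cand;
      }
      M[idx(i, j)] = best;
    }
  }

  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int best = M[idx(i, j)];
    if (best == 0) continue;
    int chosen = -1;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = wt(bases[k], bases[j]);
      if (w == 0) continue;
      int left = (k > i) ? M[idx(i, k - 1)] : 0;
      int inner = (k + 1 <= j - 1) ? M[idx(k + 1, j - 1)] : 0;
      if (left + w + inner == best) { chosen = k; break; }
    }
    if (chosen < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      pairs[chosen] = j + 1;  // 1-based partner
      pairs[j] = chosen + 1;
      if (chosen > i) stack.push_back(std::make_pair(i, chosen - 1));
      if (chosen + 1 <= j - 1)
        stack.push_back(std::make_pair(chosen + 1, j - 1));
    }
  }

  return List::create(_["pairs"] = pairs,
                      _["score"] = M[idx(0, n - 1)]);
}
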