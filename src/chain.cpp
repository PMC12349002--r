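#include <Rcpp.h>
using namespace Rcpp;

// Best gap-limited strictly-monotone chain through anchors already oriented
// so that both rank coordinates must increase. Score = anchor count.
// Tie-breaks (must mirror the documented chaining contract): among equal
// scores prefer the chain with the smaller rank_a span, then the smaller
// starting rank_a, then the earliest anchor in (rank_a, rank_b) order.
// [[Rcpp::export(name = ".best_chain_cpp")]]
List best_chain_cpp(IntegerVector ra, IntegerVector rb, int max_gap) {
  int n = ra.size();
  if (n == 0) {
    return List::create(_["score"] = 0, _["idx"] = IntegerVector(0),
                        _["span"] = NA_INTEGER, _["start"] = NA_INTEGER);
  }
  // sort order by (ra, rb)
  IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ra[a] != ra[b]) return ra[a] < ra[b];
    return rb[a] < rb[b];
  });
  std::vector<int> sra(n), srb(n);
  for (int i = 0; i < n; ++i) { sra[i] = ra[ord[i]]; srb[i] = rb[ord[i]]; }

  std::vector<int> len(n, 1), start(n), prev(n, -1);
  for (int i = 0; i < n; ++i) start[i] = sra[i];
  for (int i = 0; i < n; ++i) {
    int jlo = 0;
    // predecessors must satisfy sra[j] >= sra[i] - max_gap
    for (int j = i - 1; j >= jlo; --j) {
      if (sra[i] - sra[j] > max_gap) break;  // sorted by ra: all earlier worse
      if (sra[j] >= sra[i]) continue;
      if (srb[j] >= srb[i]) continue;
      if (srb[i] - srb[j] > max_gap) continue;
      bool better = false;
      if (len[j] + 1 > len[i]) better = true;
      else if (len[j] + 1 == len[i] && prev[i] >= 0) {
        if (start[j] > start[prev[i]]) better = true;
        else if (start[j] == start[prev[i]] && j < prev[i]) better = true;
      }
      if (better) {
        len[i] = len[j] + 1;
        start[i] = start[j];
        prev[i] = j;
      }
    }
  }
  int best = 0;
  for (int i = 1; i < n; ++i) {
    int spi = sra[i] - start[i], spb = sra[best] - start[best];
    if (len[i] > len[best] ||
        (len[i] == len[best] && (spi < spb ||
         (spi == spb && start[i] < start[best])))) {
      best = i;
    }
  }
  std::vector<int> chain;
  for (int t = best; t != -1; t = prev[t]) chain.push_back(t);
  std::reverse(chain.begin(), chain.end());
  IntegerVector idx(chain.size());
  for (size_t k = 0; k < chain.size(); ++k) idx[k] = ord[chain[k]] + 1;
  return List::create(_["score"] = (int)chain.size(), _["idx"] = idx,
                      _["span"] = sra[best] - start[best],
                      _["start"] = start[best]);
}
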