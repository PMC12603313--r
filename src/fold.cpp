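#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick + G:U wobble over the RNA alphabet {A,C,G,U}.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum-cardinality nested base pairing (Nussinov) with hairpin loops of at
// least min_loop unpaired bases between the two members of any pair.
// Traceback is deterministic: prefer leaving i unpaired, then the smallest
// pairing partner j.
List nussinov_fold(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  if (n == 0) {
    return List::create(_["pairs"] = IntegerMatrix(0, 2),
                        _["structure"] = std::string(""),
                        _["n_pairs"] = 0);
  }
  std::vector< std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - i >= 2 ? N[i + 1][k - 1] : 0) +
                    (k < j ? N[k + 1][j] : 0);
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  // iterative traceback
  std::vector<int> partner(n, -1);
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (N[i][j] == N[i + 1][j]) {        // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {   // then smallest partner
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - i >= 2 ? N[i + 1][k - 1] : 0) +
                  (k < j ? N[k + 1][j] : 0);
      if (v == N[i][j]) {
        partner[i] = k;
        partner[k] = i;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  int np = 0;
  for (int i = 0; i < n; ++i) if (partner[i] > i) ++np;
  IntegerMatrix pairs(np, 2);
  std::string db(n, '.');
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      pairs(r, 0) = i;          // 0-based, converted in the R wrapper
      pairs(r, 1) = partner[i];
      db[i] = '(';
      db[partner[i]] = ')';
      ++r;
    }
  }
  return List::create(_["pairs"] = pairs,
                      _["structure"] = db,
                      _["n_pairs"] = np);
}
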