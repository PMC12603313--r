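#include <Rcpp.h>
using namespace Rcpp;

// Position-weighted miRNA:target complementarity penalty.
// The miRNA (5'->3') binds the transcript window antiparallel, so miRNA
// position 1 faces the 3'-most window base. Costs per alignment column:
//   Watson-Crick pair 0, G:U wobble 0.5, mismatch 1, gap 2,
// all doubled when the column consumes a miRNA position in 2..13.
// A column consuming only a window base (gap in the miRNA) is charged with the
// weight of the next miRNA position to be consumed.

static inline double wt(int i, int m) {        // i = 1-based miRNA position
  if (i > m) i = m;
  return (i >= 2 && i <= 13) ? 2.0 : 1.0;
}

static inline int pair_state(char q, char t) { // q = miRNA base, t = target base
  if ((q == 'A' && t == 'U') || (q == 'U' && t == 'A') ||
      (q == 'C' && t == 'G') || (q == 'G' && t == 'C')) return 0;   // match
  if ((q == 'G' && t == 'U') || (q == 'U' && t == 'G')) return 1;   // G:U
  return 2;                                                         // mismatch
}

static double pair_cost(char q, char t, int i, int m) {
  int st = pair_state(q, t);
  double c = (st == 0) ? 0.0 : (st == 1 ? 0.5 : 1.0);
  return c * wt(i, m);
}

// Fill the DP table for miRNA vs reversed window, return final penalty.
static double dp_fill(const std::string& mir, const std::string& rw,
                      std::vector< std::vector<double> >& D) {
  const int m = (int) mir.size(), w = (int) rw.size();
  D.assign(m + 1, std::vector<double>(w + 1, 0.0));
  for (int i = 1; i <= m; ++i) D[i][0] = D[i - 1][0] + 2.0 * wt(i, m);
  for (int j = 1; j <= w; ++j) D[0][j] = D[0][j - 1] + 2.0 * wt(1, m);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= w; ++j) {
      double d = D[i - 1][j - 1] + pair_cost(mir[i - 1], rw[j - 1], i, m);
      double u = D[i - 1][j] + 2.0 * wt(i, m);          // gap in window
      double l = D[i][j - 1] + 2.0 * wt(i + 1, m);      // gap in miRNA
      double best = d;
      if (u < best) best = u;
      if (l < best) best = l;
      D[i][j] = best;
    }
  }
  return D[m][w];
}

List site_align(std::string mirna, std::string window) {
  const int m = (int) mirna.size(), w = (int) window.size();
  std::string rw(window.rbegin(), window.rend());
  std::vector< std::vector<double> > D;
  double penalty = dp_fill(mirna, rw, D);
  // traceback: prefer diagonal, then up (consume miRNA), then left
  std::vector<int> col_i, col_j, col_state;   // state: 0 match 1 GU 2 mm 3 gap
  int i = m, j = w;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(D[i][j] - (D[i - 1][j - 1] +
                 pair_cost(mirna[i - 1], rw[j - 1], i, m))) < eps) {
      col_i.push_back(i); col_j.push_back(j);
      col_state.push_back(pair_state(mirna[i - 1], rw[j - 1]));
      --i; --j;
    } else if (i > 0 &&
               std::abs(D[i][j] - (D[i - 1][j] + 2.0 * wt(i, m))) < eps) {
      col_i.push_back(i); col_j.push_back(0); col_state.push_back(3);
      --i;
    } else {
      col_i.push_back(0); col_j.push_back(j); col_state.push_back(3);
      --j;
    }
  }
  std::reverse(col_i.begin(), col_i.end());
  std::reverse(col_j.begin(), col_j.end());
  std::reverse(col_state.begin(), col_state.end());
  // window position (1-based, original orientation) opposite miRNA position 10:
  // if position 10 sits opposite a gap, take the last window base consumed at
  // or before that column.
  int jrev = 0, j_at_10 = NA_INTEGER;
  for (size_t k = 0; k < col_i.size(); ++k) {
    if (col_j[k] > 0) jrev = col_j[k];
    if (col_i[k] == 10) { j_at_10 = (jrev > 0) ? jrev : NA_INTEGER; break; }
  }
  int cleavage = (j_at_10 == NA_INTEGER || m < 10) ? NA_INTEGER
                                                   : (w - j_at_10 + 1);
  return List::create(_["penalty"] = penalty,
                      _["col_mirna"] = IntegerVector(col_i.begin(), col_i.end()),
                      _["col_window_rev"] = IntegerVector(col_j.begin(), col_j.end()),
                      _["col_state"] = IntegerVector(col_state.begin(), col_state.end()),
                      _["cleavage_window_pos"] = cleavage);
}

// Scan all windows of a transcript whose length is within |mirna| +/- max_bulge
// and return those with penalty <= max_penalty.
DataFrame site_scan(std::string mirna, std::string transcript,
                    int max_bulge, double max_penalty) {
  const int m = (int) mirna.size(), L = (int) transcript.size();
  std::vector<int> starts, lens;
  std::vector<double> pens;
  std::vector< std::vector<double> > D;
  for (int len = std::max(1, m - max_bulge); len <= m + max_bulge; ++len) {
    for (int s = 0; s + len <= L; ++s) {
      std::string win = transcript.substr(s, len);
      std::string rw(win.rbegin(), win.rend());
      double p = dp_fill(mirna, rw, D);
      if (p <= max_penalty) {
        starts.push_back(s);            // 0-based
        lens.push_back(len);
        pens.push_back(p);
      }
    }
  }
  return DataFrame::create(_["start0"] = IntegerVector(starts.begin(), starts.end()),
                           _["width"] = IntegerVector(lens.begin(), lens.end()),
                           _["penalty"] = NumericVector(pens.begin(), pens.end()));
}
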