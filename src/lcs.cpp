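#include <Rcpp.h>
#include <string>
#include <vector>

// Longest exact common substring by O(n*m) dynamic programming over two
// rolling rows. Serves as the independent oracle for the k-mer
// seed-and-extend matcher used by the prophage-exchange stage.
// [[Rcpp::export]]
int lcs_length_dp(std::string a, std::string b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

// Mean pairwise-incompatibility statistic over in-window pairs of
// parsimony-informative sites. m is sequences x informative-sites with
// states coded 0 (missing/ambiguous) or 1..4; pos gives each column's
// alignment position. The pair score is the number of observed joint
// states in excess of k1 + k2 - 1 (0 = compatible). Returns -1 when no
// pair falls within the window.
// [[Rcpp::export]]
double phi_stat_cpp(Rcpp::IntegerMatrix m, Rcpp::IntegerVector pos,
                    int window) {
  const int nseq = m.nrow(), k = m.ncol();
  double total = 0.0;
  long npairs = 0;
  for (int i = 0; i < k - 1; ++i) {
    for (int j = i + 1; j < k && pos[j] - pos[i] <= window; ++j) {
      bool seen1[5] = {false}, seen2[5] = {false}, joint[25] = {false};
      int k1 = 0, k2 = 0, nj = 0, nrows = 0;
      for (int r = 0; r < nseq; ++r) {
        int a = m(r, i), b = m(r, j);
        if (a == 0 || b == 0) continue;
        ++nrows;
        if (!seen1[a]) { seen1[a] = true; ++k1; }
        if (!seen2[b]) { seen2[b] = true; ++k2; }
        int c = (a - 1) * 5 + (b - 1);
        if (!joint[c]) { joint[c] = true; ++nj; }
      }
      int score = 0;
      if (nrows >= 4) {
        score = nj - (k1 + k2 - 1);
        if (score < 0) score = 0;
      }
      total += score;
      ++npairs;
    }
  }
  if (npairs == 0) return -1.0;
  return total / npairs;
}
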