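#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bases are compared literally; anything that is not an exact character match
// (including N vs N) scores as a mismatch, so ambiguous bases can never
// create overlap evidence.
static inline bool base_match(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// Best global alignment score of (some suffix of a) vs (some prefix of b).
// Rows follow a with a free start (D[i][0] = 0: the alignment may begin after
// skipping any prefix of a), columns follow b with penalized leading gaps
// (D[0][j] = j*gap: consuming b before a starts is an internal gap).  The
// answer is max over the last row, i.e. over all prefixes of b (j = 0 gives
// the empty overlap, score 0).
static double suffix_prefix_score(const std::string& a, const std::string& b,
                                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double up   = prev[j] + gap;
      double left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    // free start in a: D[i][0] = 0 already set each row
    std::swap(prev, cur);
  }
  double best = 0.0;
  for (int j = 0; j <= m; ++j) best = std::max(best, prev[j]);
  return best;
}

// [[Rcpp::export(name = ".overlap_score_cpp")]]
double overlap_score_cpp(std::string a, std::string b,
                         double match, double mismatch, double gap) {
  double s1 = suffix_prefix_score(a, b, match, mismatch, gap);
  double s2 = suffix_prefix_score(b, a, match, mismatch, gap);
  return std::max(0.0, std::max(s1, s2));
}

// Full Needleman-Wunsch with traceback.  Returns the optimal score, the
// number of matched columns, total alignment columns, and the edit
// transcript over {M,X,I,D} where I = base present only in a, D = base
// present only in b.  Ties resolve diagonal > up > left (leftmost-style).
// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b,
                      double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix D(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) D(i, 0) = i * gap;
  for (int j = 0; j <= m; ++j) D(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = D(i - 1, j - 1) + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double up   = D(i - 1, j) + gap;
      double left = D(i, j - 1) + gap;
      D(i, j) = std::max(diag, std::max(up, left));
    }
  }
  std::string ops;
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double diag = D(i - 1, j - 1) + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      if (D(i, j) == diag) {
        bool mt = base_match(a[i - 1], b[j - 1]);
        ops.push_back(mt ? 'M' : 'X');
        if (mt) ++matches;
        --i; --j; ++cols;
        continue;
      }
    }
    if (i > 0 && D(i, j) == D(i - 1, j) + gap) {
      ops.push_back('I'); --i; ++cols;
    } else {
      ops.push_back('D'); --j; ++cols;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = D(n, m), _["matches"] = matches,
                      _["columns"] = cols, _["transcript"] = ops);
}

// One step of incremental fit alignment used by the seed-and-extend search.
// `col` is the current DP column for query q (length n+1, col[i] = best score
// aligning q[1..i] against the context consumed so far, query start and
// context start both anchored).  Appending segment `seg` base by base yields
// one new column per base; the "complete" score after base j is col_j[n]
// (whole query consumed, context end free).  Returns the final column, the
// vector of complete scores (one per segment base), and an optimistic bound
// on any future complete score: max_i col[i] + match*(n-i).
// [[Rcpp::export(name = ".extend_cols_cpp")]]
List extend_cols_cpp(NumericVector col, std::string q, std::string seg,
                     double match, double mismatch, double gap) {
  const int n = q.size(), m = seg.size();
  std::vector<double> prev(col.begin(), col.end()), cur(n + 1);
  NumericVector complete(m);
  for (int j = 1; j <= m; ++j) {
    cur[0] = prev[0] + gap;
    for (int i = 1; i <= n; ++i) {
      double diag = prev[i - 1] + (base_match(q[i - 1], seg[j - 1]) ? match : mismatch);
      double left = prev[i] + gap;   // consume context base only
      double up   = cur[i - 1] + gap; // consume query base only
      cur[i] = std::max(diag, std::max(left, up));
    }
    complete[j - 1] = cur[n];
    std::swap(prev, cur);
  }
  NumericVector out(n + 1);
  double bound = R_NegInf;
  for (int i = 0; i <= n; ++i) {
    out[i] = prev[i];
    bound = std::max(bound, prev[i] + match * (n - i));
  }
  return List::create(_["col"] = out, _["complete"] = complete, _["bound"] = bound);
}
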