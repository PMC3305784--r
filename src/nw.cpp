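#include <Rcpp.h>
#include <climits>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
// States: M (diagonal, both residues), X (vertical, residue of `a` over a gap
// in `b`), Y (horizontal, gap in `a`). A gap of length g costs
// gap_open + g * gap_extend, so opening a length-1 gap costs
// gap_open + gap_extend. End gaps are penalized (true global alignment).
//
// Tie-break, fixed so the traceback (hence n_match / length and the genetic
// distance) is deterministic: state preference M > X > Y, both when choosing
// the final state and when choosing each predecessor.

static const int NEG_INF = INT_MIN / 4;

static inline bool is_match(char x, char y) {
  // N is scored as a mismatch against everything, including N.
  return x == y && x != 'N';
}

struct NWResult {
  int score;
  int n_match;
  int length;
  std::string aligned_a;
  std::string aligned_b;
};

static NWResult nw_core(const std::string& a, const std::string& b,
                        int match, int mismatch, int gap_open, int gap_extend,
                        bool want_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  std::vector<int> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  // predecessor state per cell: 0 = M, 1 = X, 2 = Y
  std::vector<unsigned char> pM((n + 1) * w), pX((n + 1) * w), pY((n + 1) * w);

  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = -(gap_open + i * gap_extend);
    pX[i * w] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_extend);
    pY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
                l = i * w + (j - 1), c = i * w + j;
      // M: best predecessor at (i-1, j-1), preference M > X > Y on ties
      int best = M[d];
      unsigned char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      if (best > NEG_INF) {
        M[c] = best + (is_match(ai, b[j - 1]) ? match : mismatch);
        pM[c] = arg;
      }
      // X: consume a[i-1] against a gap
      best = (M[u] > NEG_INF) ? M[u] - gap_open - gap_extend : NEG_INF;
      arg = 0;
      if (X[u] > NEG_INF && X[u] - gap_extend > best) {
        best = X[u] - gap_extend; arg = 1;
      }
      if (Y[u] > NEG_INF && Y[u] - gap_open - gap_extend > best) {
        best = Y[u] - gap_open - gap_extend; arg = 2;
      }
      if (best > NEG_INF) { X[c] = best; pX[c] = arg; }
      // Y: consume b[j-1] against a gap
      best = (M[l] > NEG_INF) ? M[l] - gap_open - gap_extend : NEG_INF;
      arg = 0;
      if (X[l] > NEG_INF && X[l] - gap_open - gap_extend > best) {
        best = X[l] - gap_open - gap_extend; arg = 1;
      }
      if (Y[l] > NEG_INF && Y[l] - gap_extend > best) {
        best = Y[l] - gap_extend; arg = 2;
      }
      if (best > NEG_INF) { Y[c] = best; pY[c] = arg; }
    }
  }

  const int end = n * w + m;
  int state = 0, score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // traceback
  NWResult res;
  res.score = score;
  res.n_match = 0;
  res.length = 0;
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * w + j;
    int prev;
    if (state == 0) {
      prev = pM[c];
      if (want_strings) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      if (is_match(a[i - 1], b[j - 1])) ++res.n_match;
      --i; --j;
    } else if (state == 1) {
      prev = pX[c];
      if (want_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
    } else {
      prev = pY[c];
      if (want_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
    }
    ++res.length;
    state = prev;
  }
  if (want_strings) {
    res.aligned_a.assign(ra.rbegin(), ra.rend());
    res.aligned_b.assign(rb.rbegin(), rb.rend());
  }
  return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  NWResult r = nw_core(a, b, match, mismatch, gap_open, gap_extend, true);
  return List::create(_["aligned_a"] = r.aligned_a, _["aligned_b"] = r.aligned_b,
                      _["score"] = r.score, _["n_match"] = r.n_match,
                      _["length"] = r.length);
}

// Genetic distances 1 - n_match/length for a list of index pairs (1-based
// into `seqs`). Used by the all-pairs and anchor-distance drivers.
// [[Rcpp::export]]
NumericVector nw_distance_pairs_cpp(CharacterVector seqs, IntegerVector ii,
                                    IntegerVector jj, int match, int mismatch,
                                    int gap_open, int gap_extend) {
  if (ii.size() != jj.size()) stop("pair index vectors differ in length");
  std::vector<std::string> s(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) s[k] = as<std::string>(seqs[k]);
  NumericVector out(ii.size());
  for (int k = 0; k < ii.size(); ++k) {
    const int i = ii[k] - 1, j = jj[k] - 1;
    if (i < 0 || j < 0 || i >= (int)s.size() || j >= (int)s.size())
      stop("pair index out of range");
    NWResult r = nw_core(s[i], s[j], match, mismatch, gap_open, gap_extend, false);
    out[k] = 1.0 - (double)r.n_match / (double)r.length;
  }
  return out;
}
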