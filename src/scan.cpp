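#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Best log-odds window per sequence.
//
// seqs:    list of integer vectors, codes 1..4 = A,C,G,T, 0 = invalid letter
// mats:    list of K 4 x W column-stochastic path matrices (see tpwm_paths);
//          the model probability of a word is sum_k w_k prod_i M_k[a_i, i]
// weights: K path weights summing to 1
// bg:      length-4 background probabilities (order 0)
// both:    also scan the reverse-complement orientation of every window
//
// Ties are broken toward the smaller start, then the forward strand (the
// forward window of an offset is examined before the reverse one).
// Windows containing an invalid letter are skipped; a sequence with no
// valid window gets score NA, start -1, strand 0.
// [[Rcpp::export]]
List scan_best_cpp(List seqs, List mats, NumericVector weights,
                   NumericVector bg, bool both) {
  const int K = mats.size();
  int W = 0;
  std::vector<const double*> M(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix mk = mats[k];
    if (k == 0) W = mk.ncol();
    M[k] = REAL(mk);
  }
  double lbg[5], lbgc[5];
  for (int a = 1; a <= 4; ++a) {
    lbg[a]  = std::log2(bg[a - 1]);
    lbgc[a] = std::log2(bg[4 - a]);  // background prob of the complement
  }

  const int n = seqs.size();
  NumericVector best_score(n);
  IntegerVector best_start(n), best_strand(n);

  for (int s = 0; s < n; ++s) {
    IntegerVector sv = seqs[s];
    const int L = sv.size();
    const int* a = INTEGER(sv);
    double bscore = R_NegInf;
    int bstart = -1, bstrand = 0;
    bool found = false;
    for (int o = 0; o + W <= L; ++o) {
      bool valid = true;
      for (int i = 0; i < W; ++i) {
        if (a[o + i] == 0) { valid = false; break; }
      }
      if (!valid) continue;
      // forward strand
      double p = 0.0, bgsum = 0.0;
      for (int k = 0; k < K; ++k) {
        double prod = weights[k];
        const double* mk = M[k];
        for (int i = 0; i < W; ++i) prod *= mk[(a[o + i] - 1) + 4 * i];
        p += prod;
      }
      for (int i = 0; i < W; ++i) bgsum += lbg[a[o + i]];
      double sc = std::log2(p) - bgsum;
      if (!found || sc > bscore) {
        bscore = sc; bstart = o; bstrand = 1; found = true;
      }
      if (both) {
        // reverse complement word: position i reads complement of a[o+W-1-i]
        p = 0.0; bgsum = 0.0;
        for (int k = 0; k < K; ++k) {
          double prod = weights[k];
          const double* mk = M[k];
          for (int i = 0; i < W; ++i) {
            prod *= mk[(4 - a[o + W - 1 - i]) + 4 * i];
          }
          p += prod;
        }
        for (int i = 0; i < W; ++i) bgsum += lbgc[a[o + i]];
        sc = std::log2(p) - bgsum;
        if (!found || sc > bscore) {
          bscore = sc; bstart = o; bstrand = 2; found = true;
        }
      }
    }
    best_score[s] = found ? bscore : NA_REAL;
    best_start[s] = bstart;
    best_strand[s] = bstrand;
  }
  return List::create(_["score"] = best_score, _["start"] = best_start,
                      _["strand"] = best_strand);
}
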