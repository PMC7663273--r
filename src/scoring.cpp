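#include <Rcpp.h>
using namespace Rcpp;

// Positional scores S_p of an encoded query q against an encoded training
// sequence k: S_p = max over all full frames covering p at all shifts of
// the frame's identity-match count.  One pass per diagonal (shift) keeps a
// running window sum; each window raises S_p for the F positions it covers.
// Residue codes <= 0 never match (ambiguous residues).
// [[Rcpp::export(name = ".positional_scores_cpp")]]
NumericVector positional_scores_cpp(IntegerVector q, IntegerVector k, int frame) {
  const int m = q.size(), n = k.size(), F = frame;
  NumericVector S(m);
  for (int h = F - m; h <= n - F; ++h) {
    int imin = std::max(0, -h);              // 0-based start in q
    int imax = std::min(m - F, n - F - h);
    if (imin > imax) continue;
    int run = 0;
    for (int j = imin; j < imin + F; ++j)
      run += (q[j] > 0 && q[j] == k[j + h]);
    for (int i = imin; i <= imax; ++i) {
      if (i > imin) {
        run -= (q[i - 1] > 0 && q[i - 1] == k[i - 1 + h]);
        int j = i + F - 1;
        run += (q[j] > 0 && q[j] == k[j + h]);
      }
      if (run > 0) {
        int pend = i + F - 1;
        for (int p = i; p <= pend; ++p)
          if (run > S[p]) S[p] = run;
      }
    }
  }
  return S;
}
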