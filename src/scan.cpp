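#include <Rcpp.h>
using namespace Rcpp;

// PWM log-odds scan of equal-length encoded sequences (codes 1..5, 5 = N).
// lo is a 5 x w log-odds matrix (row 5 zero). Returns all windows with
// score >= thr as parallel vectors (sequence index, start index, score),
// both 1-based.
// [[Rcpp::export(name = ".scan_hits_cpp")]]
List scan_hits_cpp(IntegerMatrix B, NumericMatrix lo, double thr) {
  const int n = B.nrow(), L = B.ncol(), w = lo.ncol();
  const int npos = L - w + 1;
  std::vector<int> cols;       // informative PWM columns only
  for (int j = 0; j < w; ++j) {
    bool zero = true;
    for (int b = 0; b < 5; ++b)
      if (std::fabs(lo(b, j)) > 1e-12) { zero = false; break; }
    if (!zero) cols.push_back(j);
  }
  std::vector<int> out_i, out_s;
  std::vector<double> out_score;
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < npos; ++s) {
      double sc = 0.0;
      for (size_t c = 0; c < cols.size(); ++c) {
        const int j = cols[c];
        sc += lo(B(i, s + j) - 1, j);
      }
      if (sc >= thr) {
        out_i.push_back(i + 1);
        out_s.push_back(s + 1);
        out_score.push_back(sc);
      }
    }
  }
  return List::create(_["seq"] = wrap(out_i), _["start"] = wrap(out_s),
                      _["score"] = wrap(out_score));
}
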