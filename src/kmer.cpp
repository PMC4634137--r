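#include <Rcpp.h>
using namespace Rcpp;

// Rolling k-mer counter over encoded sequences (codes 1..5, 5 = N).
// Collapses each k-mer with its reverse complement into a canonical class
// (the smaller of the two 2-bit-packed codes). Windows containing N are
// skipped. Returns one row per (sequence, class) pair with its occurrence
// count. k <= 15 keeps codes inside a 32-bit int.
// [[Rcpp::export(name = ".kmer_counts_cpp")]]
List kmer_counts_cpp(IntegerMatrix B, int k) {
  const int n = B.nrow(), L = B.ncol();
  if (k > 15) stop("k must be <= 15");
  const int npos = L - k + 1;
  const unsigned int mask = (1u << (2 * k)) - 1u;
  const int shift_rc = 2 * (k - 1);
  std::vector<int> counts(1u << (2 * k), 0);
  std::vector<unsigned int> touched;
  std::vector<int> out_gene, out_class, out_count;
  for (int i = 0; i < n; ++i) {
    unsigned int code = 0, rc = 0;
    int valid = 0;  // length of current N-free suffix
    touched.clear();
    for (int s = 0; s < L; ++s) {
      const int b = B(i, s) - 1;  // 0..3 or 4 for N
      if (b > 3) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (unsigned int)b) & mask;
      rc = (rc >> 2) | ((unsigned int)(3 - b) << shift_rc);
      if (++valid >= k) {
        const unsigned int canon = code < rc ? code : rc;
        if (counts[canon]++ == 0) touched.push_back(canon);
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      out_gene.push_back(i + 1);
      out_class.push_back((int)touched[t]);
      out_count.push_back(counts[touched[t]]);
      counts[touched[t]] = 0;
    }
  }
  (void)npos;
  return List::create(_["gene"] = wrap(out_gene),
                      _["class"] = wrap(out_class),
                      _["count"] = wrap(out_count));
}
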