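#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local alignment of a window against a cyclic (wraparound) consensus.
//
// Bases are encoded 0..3 = A,C,G,T and 4 = N; N always scores as a mismatch.
// The consensus index wraps modulo its length, so an array of tandem copies
// aligns copy after copy against the same short consensus.  Row 0 is all
// zeros (free start phase) and cells floor at zero, i.e. the alignment is
// local within the window: flanking non-repetitive sequence is excluded and
// a noise-free array scores exactly match_weight * array_length.
//
// Each row is computed in two passes so that a chain of consensus deletions
// ("left" moves) may wrap once across the j = 0 boundary; because the indel
// penalty is positive a chain never profits from wrapping a full cycle, so
// two passes suffice.
//
// [[Rcpp::export]]
List wrap_dp(IntegerVector w, IntegerVector cons,
             int match, int mismatch, int indel) {
  const int n = w.size();
  const int p = cons.size();
  if (p < 1) stop("consensus must be non-empty");
  if (n < 1) stop("window must be non-empty");

  const double NEG = -1e18;
  std::vector<double> prev(p, 0.0), cur(p, 0.0);
  // direction codes: 0 = stop (local restart), 1 = diag, 2 = up (insertion
  // in window), 3 = left (deletion of a consensus column)
  std::vector<unsigned char> dir((size_t)(n + 1) * p, 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int wi = w[i - 1];
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < p; ++j) {
        const int jm = (j == 0) ? p - 1 : j - 1;
        const double sc = (wi == cons[j] && wi < 4 && cons[j] < 4)
                            ? (double)match : -(double)mismatch;
        const double d = prev[jm] + sc;
        const double u = prev[j] - indel;
        const double l = ((pass == 0 && j == 0) ? NEG : cur[jm]) - indel;
        double m = d; unsigned char dd = 1;
        if (u > m) { m = u; dd = 2; }
        if (l > m) { m = l; dd = 3; }
        if (0.0 >= m) { m = 0.0; dd = 0; }
        if (pass == 0 || m > cur[j]) {
          cur[j] = m;
          dir[(size_t)i * p + j] = dd;
        }
      }
    }
    for (int j = 0; j < p; ++j) {
      if (cur[j] > best) { best = cur[j]; bi = i; bj = j; }
      prev[j] = cur[j];
    }
  }

  IntegerVector path_col(n, -9);   // consensus column per window base, -1 = inserted
  IntegerVector ins_after(n, -1);  // for inserted bases: consensus column they follow
  IntegerVector del_count(p, 0);
  int n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0;

  int i = bi, j = bj;
  while (i > 0) {
    const unsigned char dd = dir[(size_t)i * p + j];
    if (dd == 0) break;
    if (dd == 1) {
      path_col[i - 1] = j;
      if (w[i - 1] == cons[j] && w[i - 1] < 4) ++n_match; else ++n_mismatch;
      --i; j = (j == 0) ? p - 1 : j - 1;
    } else if (dd == 2) {
      path_col[i - 1] = -1;
      ins_after[i - 1] = j;
      ++n_ins;
      --i;
    } else {
      ++del_count[j];
      ++n_del;
      j = (j == 0) ? p - 1 : j - 1;
    }
  }

  return List::create(
    _["score"] = best,
    _["i_start"] = i + 1,   // 1-based first aligned window position
    _["i_end"] = bi,        // 1-based last aligned window position
    _["n_match"] = n_match,
    _["n_mismatch"] = n_mismatch,
    _["n_ins"] = n_ins,
    _["n_del"] = n_del,
    _["path_col"] = path_col,
    _["ins_after"] = ins_after,
    _["del_count"] = del_count);
}
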