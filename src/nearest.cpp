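#include <Rcpp.h>
using namespace Rcpp;

// Exact Euclidean nearest reference cell for each query cell, with a
// deterministic tie-break toward the smallest reference index. Coordinates
// are cell centres; distances are compared as squared integer offsets so
// ties are exact.
// [[Rcpp::export]]
IntegerVector nearest_ref_cell(IntegerVector q_row, IntegerVector q_col,
                               IntegerVector r_row, IntegerVector r_col) {
  const int nq = q_row.size(), nr = r_row.size();
  if (nr == 0) stop("no reference cells");
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    long long best = -1;
    int best_j = -1;
    for (int j = 0; j < nr; ++j) {
      long long dr = q_row[i] - r_row[j], dc = q_col[i] - r_col[j];
      long long d2 = dr * dr + dc * dc;
      if (best_j < 0 || d2 < best) {
        best = d2;
        best_j = j;
      }
    }
    out[i] = best_j + 1; // 1-based
  }
  return out;
}
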