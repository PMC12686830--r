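#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbour between two 3D point sets.
// Desk-scale clouds (<= a few thousand points) make an O(n*m) scan in C++
// faster and simpler than a tree; distances are exact, not approximate.
// [[Rcpp::export(name = ".nn_bruteforce")]]
List nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != 3 || ref.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (nr == 0) stop("reference set is empty");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx;
      const double dy = ref(j, 1) - qy;
      const double dz = ref(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = j; }
    }
    idx[i] = besti + 1;       // 1-based for R
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Squared-distance matrix between two 3D point sets (M x N), used by the
// coherent-point-drift E-step where the full matrix is needed anyway.
// [[Rcpp::export(name = ".dist2_matrix")]]
NumericMatrix dist2_matrix(NumericMatrix a, NumericMatrix b) {
  const int m = a.nrow(), n = b.nrow();
  if (a.ncol() != 3 || b.ncol() != 3)
    stop("point matrices must have 3 columns");
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j) {
    const double bx = b(j, 0), by = b(j, 1), bz = b(j, 2);
    for (int i = 0; i < m; ++i) {
      const double dx = a(i, 0) - bx;
      const double dy = a(i, 1) - by;
      const double dz = a(i, 2) - bz;
      out(i, j) = dx * dx + dy * dy + dz * dz;
    }
  }
  return out;
}
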