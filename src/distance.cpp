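#include <Rcpp.h>
using namespace Rcpp;

// Greedy two-pointer matching on sorted allele vectors. For interval
// tolerance (|x - y| <= tol) on a line this greedy is a maximum matching;
// the R test suite verifies it against brute-force enumeration.
static inline int match_count(const int* a, int na, const int* b, int nb, int tol) {
  int i = 0, j = 0, m = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < 0) d = -d;
    if (d <= tol) { ++m; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return m;
}

// alleles: all AFLs concatenated sample-major, each sample's per-marker block
// sorted ascending. starts/lens: n_samples x n_markers (column-major via
// IntegerMatrix) giving each block's offset (0-based) and length.
// [[Rcpp::export(name = ".dist_matrix_cpp")]]
List dist_matrix_cpp(IntegerVector alleles, IntegerMatrix starts,
                     IntegerMatrix lens, int tol) {
  const int n = starts.nrow();
  const int nm = starts.ncol();
  NumericMatrix d(n, n);
  std::vector<std::pair<int, int> > undefined;
  const int* av = INTEGER(alleles);

  // total allele count per sample (denominator contributions)
  std::vector<int> tot(n, 0);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < nm; ++m) tot[i] += lens(i, m);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int common = 0, denom = 0;
      for (int m = 0; m < nm; ++m) {
        int li = lens(i, m), lj = lens(j, m);
        if (li == 0 && lj == 0) continue;  // both-null markers drop out entirely
        denom += li + lj;
        if (li > 0 && lj > 0)
          common += match_count(av + starts(i, m), li, av + starts(j, m), lj, tol);
      }
      double val;
      if (denom == 0) {  // both profiles entirely null: distance undefined
        val = 1.0;
        undefined.push_back(std::make_pair(i + 1, j + 1));
      } else {
        val = 1.0 - (2.0 * common) / denom;
      }
      d(i, j) = val;
      d(j, i) = val;
    }
  }
  IntegerMatrix und(undefined.size(), 2);
  for (size_t k = 0; k < undefined.size(); ++k) {
    und(k, 0) = undefined[k].first;
    und(k, 1) = undefined[k].second;
  }
  return List::create(_["d"] = d, _["undefined_pairs"] = und);
}
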