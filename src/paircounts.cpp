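#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive O(n^2) tally of concordant/discordant/tied observation pairs.
// Tie counts follow the tau-B convention: n1 counts pairs tied on x
// (whether or not tied on y), n2 pairs tied on y, nxy pairs tied on both.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  double nc = 0, nd = 0, n1 = 0, n2 = 0, nxy = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0 && dy == 0) { n1++; n2++; nxy++; }
      else if (dx == 0)        { n1++; }
      else if (dy == 0)        { n2++; }
      else if (dx * dy > 0)    { nc++; }
      else                     { nd++; }
    }
  }
  double n0 = (double)n * (n - 1) / 2.0;
  return List::create(_["n_c"] = nc, _["n_d"] = nd, _["n_0"] = n0,
                      _["n_1"] = n1, _["n_2"] = n2, _["n_xy"] = nxy,
                      _["n"] = (double)n);
}
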