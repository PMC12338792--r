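#include <Rcpp.h>
using namespace Rcpp;

// Local maxima of a 1-D profile with topographic prominence.
//
// A local maximum is a strict rise followed by a strict fall; a flat plateau
// counts once and is reported at its shallowest (left-most) index. Endpoints
// are never peaks. Prominence follows the usual topographic definition: walk
// outwards from the peak on each side until the signal exceeds the peak value
// (or the boundary is reached), take the minimum encountered on each walk,
// and subtract the higher of the two minima from the peak value.
//
// Returns a two-column numeric matrix: 1-based peak index, prominence.
// [[Rcpp::export(name = ".peak_prominences")]]
NumericMatrix peak_prominences(NumericVector x) {
  const int n = x.size();
  std::vector<int> idx;
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      // possible plateau: advance over equal values
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1 && x[j + 1] < x[i]) idx.push_back(i);
      i = j + 1;
    } else {
      ++i;
    }
  }
  NumericMatrix out(idx.size(), 2);
  for (size_t k = 0; k < idx.size(); ++k) {
    int p = idx[k];
    double h = x[p];
    double lmin = h, rmin = h;
    for (int j = p - 1; j >= 0; --j) {
      if (x[j] > h) break;
      if (x[j] < lmin) lmin = x[j];
    }
    for (int j = p + 1; j < n; ++j) {
      if (x[j] > h) break;
      if (x[j] < rmin) rmin = x[j];
    }
    out(k, 0) = p + 1;  // 1-based
    out(k, 1) = h - std::max(lmin, rmin);
  }
  return out;
}
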