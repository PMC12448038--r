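#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected components of supra-threshold cells on the channel x frequency
// grid. Two cells are connected iff same channel & adjacent frequency bins,
// or adjacent channels (per `adj`) & same frequency bin. Positive
// (t > thresh) and negative (t < -thresh) cells form separate clusters.
// `adj`: list (length n_channels) of 1-based neighbour channel indices.
//
// Returns labels (0 = subthreshold), per-cluster summed t and sign.
// [[Rcpp::export(name = ".cluster_components")]]
List cluster_components(NumericMatrix t, double thresh, List adj) {
  const int nch = t.nrow(), nf = t.ncol();
  std::vector<std::vector<int> > nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = adj[c];
    for (int k = 0; k < v.size(); ++k) nb[c].push_back(v[k] - 1);
  }
  IntegerMatrix labels(nch, nf);
  std::vector<double> stats;
  std::vector<int> signs;
  std::vector<int> stack;
  int next = 0;
  for (int f0 = 0; f0 < nf; ++f0) {
    for (int c0 = 0; c0 < nch; ++c0) {
      if (labels(c0, f0) != 0) continue;
      double v0 = t(c0, f0);
      int sgn = v0 > thresh ? 1 : (v0 < -thresh ? -1 : 0);
      if (sgn == 0) continue;
      ++next;
      double sum = 0.0;
      stack.clear();
      stack.push_back(c0 + nch * f0);
      labels(c0, f0) = next;
      while (!stack.empty()) {
        int cell = stack.back(); stack.pop_back();
        int c = cell % nch, f = cell / nch;
        sum += t(c, f);
        // frequency neighbours, same channel
        for (int df = -1; df <= 1; df += 2) {
          int f2 = f + df;
          if (f2 < 0 || f2 >= nf || labels(c, f2) != 0) continue;
          double v = t(c, f2);
          if ((sgn > 0 && v > thresh) || (sgn < 0 && v < -thresh)) {
            labels(c, f2) = next;
            stack.push_back(c + nch * f2);
          }
        }
        // channel neighbours, same frequency
        for (size_t k = 0; k < nb[c].size(); ++k) {
          int c2 = nb[c][k];
          if (labels(c2, f) != 0) continue;
          double v = t(c2, f);
          if ((sgn > 0 && v > thresh) || (sgn < 0 && v < -thresh)) {
            labels(c2, f) = next;
            stack.push_back(c2 + nch * f);
          }
        }
      }
      stats.push_back(sum);
      signs.push_back(sgn);
    }
  }
  return List::create(_["labels"] = labels,
                      _["stats"] = NumericVector(stats.begin(), stats.end()),
                      _["signs"] = IntegerVector(signs.begin(), signs.end()));
}

// Maximum |summed t| over all clusters (both signs); 0 when no cell exceeds
// the threshold. Used inside the permutation loop.
// [[Rcpp::export(name = ".cluster_max_stat")]]
double cluster_max_stat(NumericMatrix t, double thresh, List adj) {
  List res = cluster_components(t, thresh, adj);
  NumericVector stats = res["stats"];
  double mx = 0.0;
  for (int i = 0; i < stats.size(); ++i)
    mx = std::max(mx, std::fabs(stats[i]));
  return mx;
}
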