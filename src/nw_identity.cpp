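#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs, returning the
// optimal score and the match/column counts of the traceback alignment.
// Traceback preference at score ties: diagonal, then up (gap in b), then left.
// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b,
                     double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag; unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = columns,
                      _["identity"] = columns > 0 ? (double)matches / columns : 1.0);
}
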