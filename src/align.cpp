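#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalties and a
// deterministic traceback that prefers diagonal, then up (gap in b), then
// left (gap in a) when scores tie.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);  // 0 = diag, 1 = up, 2 = left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d; int p = 0;
      if (u > best) { best = u; p = 1; }
      if (l > best) { best = l; p = 2; }
      S(i, j) = best; P(i, j) = p;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = (i > 0 && j > 0) ? P(i, j) : (i > 0 ? 1 : 2);
    if (p == 0)      { ra += a[i - 1]; rb += b[j - 1]; --i; --j; }
    else if (p == 1) { ra += a[i - 1]; rb += '-';      --i; }
    else             { ra += '-';      rb += b[j - 1]; --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = S(n, m));
}
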