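#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and a fixed,
// deterministic tie-break in the traceback: diagonal, then up (gap in the
// second sequence), then left (gap in the first).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // pointers: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> ptr((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) {
    prev[j] = j * gap;
    if (j > 0) ptr[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    ptr[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag;
      unsigned char p = 0;
      if (sup > best) { best = sup; p = 1; }
      if (sleft > best) { best = sleft; p = 2; }
      cur[j] = best;
      ptr[(size_t)i * (m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string aa, bb;
  aa.reserve(n + m);
  bb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
    } else {
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = score);
}
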