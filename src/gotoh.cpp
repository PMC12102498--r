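// Affine-gap global alignment (Gotoh) with deterministic traceback.
// State preference at equal scores: M (diagonal) > X (gap in second
// sequence) > Y (gap in first). A gap of length L costs open1 + (L-1)*ext,
// where open1 already includes the first residue's extension.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool eq(double u, double v) { return std::fabs(u - v) < 1e-9; }

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix S,
                     double open1, double ext) {
  const int n = ai.size(), m = bi.size();
  const double NEG = -1e15;
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))
  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[IDX(i, 0)] = -(open1 + ext * (i - 1));
  for (int j = 1; j <= m; ++j) Y[IDX(0, j)] = -(open1 + ext * (j - 1));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(ai[i - 1] - 1, bi[j - 1] - 1);
      const double dM = M[IDX(i - 1, j - 1)], dX = X[IDX(i - 1, j - 1)],
                   dY = Y[IDX(i - 1, j - 1)];
      M[IDX(i, j)] = s + std::max(dM, std::max(dX, dY));
      X[IDX(i, j)] = std::max(M[IDX(i - 1, j)] - open1,
                              std::max(X[IDX(i - 1, j)] - ext,
                                       Y[IDX(i - 1, j)] - open1));
      Y[IDX(i, j)] = std::max(M[IDX(i, j - 1)] - open1,
                              std::max(X[IDX(i, j - 1)] - open1,
                                       Y[IDX(i, j - 1)] - ext));
    }
  }
  double sM = M[IDX(n, m)], sX = X[IDX(n, m)], sY = Y[IDX(n, m)];
  int state = 1;
  double score = sM;
  if (sX > score) { state = 2; score = sX; }
  if (sY > score) { state = 3; score = sY; }

  std::vector<int> oa, ob; // 0 encodes a gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 3;
    else if (j == 0) state = 2;
    if (state == 1) {
      const double here = M[IDX(i, j)];
      const double prev = here - S(ai[i - 1] - 1, bi[j - 1] - 1);
      oa.push_back(ai[i - 1]);
      ob.push_back(bi[j - 1]);
      if (eq(M[IDX(i - 1, j - 1)], prev)) state = 1;
      else if (eq(X[IDX(i - 1, j - 1)], prev)) state = 2;
      else state = 3;
      --i; --j;
    } else if (state == 2) {
      const double here = X[IDX(i, j)];
      oa.push_back(ai[i - 1]);
      ob.push_back(0);
      if (eq(M[IDX(i - 1, j)] - open1, here)) state = 1;
      else if (eq(X[IDX(i - 1, j)] - ext, here)) state = 2;
      else state = 3;
      --i;
    } else {
      const double here = Y[IDX(i, j)];
      oa.push_back(0);
      ob.push_back(bi[j - 1]);
      if (eq(M[IDX(i, j - 1)] - open1, here)) state = 1;
      else if (eq(X[IDX(i, j - 1)] - open1, here)) state = 2;
      else state = 3;
      --j;
    }
  }
#undef IDX
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(Named("score") = score,
                      Named("a") = IntegerVector(oa.begin(), oa.end()),
                      Named("b") = IntegerVector(ob.begin(), ob.end()));
}
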