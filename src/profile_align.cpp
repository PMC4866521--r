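#include <Rcpp.h>
using namespace Rcpp;

// Global (Gotoh) alignment of a profile against a sequence given a
// precomputed match-score matrix S (profile columns x sequence positions).
// Affine gaps: a run of k gapped positions costs gapOpen + k * gapExtend.
// Returns a 2-column integer matrix of 1-based indices along the alignment
// path; 0 marks a gap on that side.  The optimal score is attached as the
// "score" attribute.
// [[Rcpp::export]]
IntegerMatrix c_affine_align(NumericMatrix S, double gapOpen,
                             double gapExtend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e30;
  const double openCost = gapOpen + gapExtend;

  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);
  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -(gapOpen + i * gapExtend);
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -(gapOpen + j * gapExtend);
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = std::max(M(i - 1, j - 1),
                             std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      M(i, j) = S(i - 1, j - 1) + diag;
      Ix(i, j) = std::max(M(i - 1, j) - openCost, Ix(i - 1, j) - gapExtend);
      Iy(i, j) = std::max(M(i, j - 1) - openCost, Iy(i, j - 1) - gapExtend);
    }
  }

  double best = M(m, n);
  int state = 0; // 0 = M (match), 1 = Ix (gap in sequence), 2 = Iy
  if (Ix(m, n) > best) { best = Ix(m, n); state = 1; }
  if (Iy(m, n) > best) { best = Iy(m, n); state = 2; }

  const double eps = 1e-9;
  std::vector<int> pi, pj;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (j == 0) {                 // only profile columns remain
      pi.push_back(i); pj.push_back(0); --i;
    } else if (i == 0) {          // only sequence positions remain
      pi.push_back(0); pj.push_back(j); --j;
    } else if (state == 0) {
      pi.push_back(i); pj.push_back(j);
      double prev = M(i, j) - S(i - 1, j - 1);
      if (std::abs(prev - M(i - 1, j - 1)) < eps) state = 0;
      else if (std::abs(prev - Ix(i - 1, j - 1)) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      pi.push_back(i); pj.push_back(0);
      state = (std::abs(Ix(i, j) - (M(i - 1, j) - openCost)) < eps) ? 0 : 1;
      --i;
    } else {
      pi.push_back(0); pj.push_back(j);
      state = (std::abs(Iy(i, j) - (M(i, j - 1) - openCost)) < eps) ? 0 : 2;
      --j;
    }
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  path.attr("score") = best;
  return path;
}
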