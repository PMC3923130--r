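#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs, Gotoh
// three-state recursion. Gap of length L costs gap_open + L * gap_extend
// (both <= 0). Tie-breaking is deterministic: aligned pair (M) is
// preferred over a gap in A (X), which is preferred over a gap in B (Y),
// both when choosing the final state and throughout the traceback.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char a, char b, double match, double mismatch) {
  return (a == b) ? match : mismatch;
}

// state codes: 0 = M (aligned pair), 1 = X (gap in A), 2 = Y (gap in B)
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // predecessor state of each cell per state, for traceback
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; Y(0, j) = NEG_INF;
    X(0, j) = gap_open + j * gap_extend;
    pX(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; X(i, 0) = NEG_INF;
    Y(i, 0) = gap_open + i * gap_extend;
    pY(i, 0) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move from best of the three states
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double best = M(i - 1, j - 1); int st = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); st = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); st = 2; }
      M(i, j) = best + s; pM(i, j) = st;

      // X: gap in A, consumes b[j-1]
      double oM = M(i, j - 1) + gap_open + gap_extend;
      double oX = X(i, j - 1) + gap_extend;
      double oY = Y(i, j - 1) + gap_open + gap_extend;
      best = oM; st = 0;
      if (oX > best) { best = oX; st = 1; }
      if (oY > best) { best = oY; st = 2; }
      X(i, j) = best; pX(i, j) = st;

      // Y: gap in B, consumes a[i-1]
      oM = M(i - 1, j) + gap_open + gap_extend;
      oX = X(i - 1, j) + gap_open + gap_extend;
      oY = Y(i - 1, j) + gap_extend;
      best = oM; st = 0;
      if (oX > best) { best = oX; st = 1; }
      if (oY > best) { best = oY; st = 2; }
      Y(i, j) = best; pY(i, j) = st;
    }
  }

  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::string outA, outB;
  outA.reserve(n + m); outB.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM(i, j);
      outA.push_back(a[i - 1]); outB.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = pX(i, j);
      outA.push_back('-'); outB.push_back(b[j - 1]);
      --j; state = prev;
    } else {
      int prev = pY(i, j);
      outA.push_back(a[i - 1]); outB.push_back('-');
      --i; state = prev;
    }
  }
  std::reverse(outA.begin(), outA.end());
  std::reverse(outB.begin(), outB.end());

  return List::create(_["score"] = score,
                      _["alignedA"] = outA,
                      _["alignedB"] = outB);
}
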