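#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment of two alignment profiles.
// Profiles are 20 x L matrices of per-column residue frequencies (columns
// may sum to < 1 when rows carry gaps; gappy columns then score less).
// Column-pair score: fA' * S * fB.  Returns 1-based column paths with 0
// marking a gap, suitable for stitching two sub-alignments together.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double gap_open, double gap_ext) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  // Precompute S * fB for each column of B
  NumericMatrix SB(20, lb);
  for (int j = 0; j < lb; ++j)
    for (int a = 0; a < 20; ++a) {
      double s = 0.0;
      for (int b = 0; b < 20; ++b) s += S(a, b) * B(b, j);
      SB(a, j) = s;
    }

  std::vector<std::vector<double>> M(la + 1, std::vector<double>(lb + 1, NEG)),
      X(la + 1, std::vector<double>(lb + 1, NEG)),   // gap in B (A advances)
      Y(la + 1, std::vector<double>(lb + 1, NEG));
  std::vector<std::vector<signed char>> tbM(la + 1, std::vector<signed char>(lb + 1, 0)),
      tbX(la + 1, std::vector<signed char>(lb + 1, 0)),
      tbY(la + 1, std::vector<signed char>(lb + 1, 0));

  M[0][0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[i][0] = -gap_open - gap_ext * i;
    tbX[i][0] = (i == 1) ? 0 : 1; // from M at origin, else extend
  }
  for (int j = 1; j <= lb; ++j) {
    Y[0][j] = -gap_open - gap_ext * j;
    tbY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double sc = 0.0;
      for (int a = 0; a < 20; ++a) sc += A(a, i - 1) * SB(a, j - 1);
      // M
      double m0 = M[i - 1][j - 1], m1 = X[i - 1][j - 1], m2 = Y[i - 1][j - 1];
      if (m0 >= m1 && m0 >= m2) { M[i][j] = m0 + sc; tbM[i][j] = 0; }
      else if (m1 >= m2)        { M[i][j] = m1 + sc; tbM[i][j] = 1; }
      else                      { M[i][j] = m2 + sc; tbM[i][j] = 2; }
      // X: consume column of A against gap
      double xo = M[i - 1][j] - gap_open - gap_ext;
      double xe = X[i - 1][j] - gap_ext;
      if (xo >= xe) { X[i][j] = xo; tbX[i][j] = 0; } else { X[i][j] = xe; tbX[i][j] = 1; }
      // Y: consume column of B against gap
      double yo = M[i][j - 1] - gap_open - gap_ext;
      double ye = Y[i][j - 1] - gap_ext;
      if (yo >= ye) { Y[i][j] = yo; tbY[i][j] = 0; } else { Y[i][j] = ye; tbY[i][j] = 2; }
    }
  }

  int state; double best = M[la][lb]; state = 0;
  if (X[la][lb] > best) { best = X[la][lb]; state = 1; }
  if (Y[la][lb] > best) { best = Y[la][lb]; state = 2; }

  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[i][j];
      pa.push_back(i); pb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[i][j];
      pa.push_back(i); pb.push_back(0); --i; state = prev;
    } else {
      int prev = tbY[i][j];
      pa.push_back(0); pb.push_back(j); --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb),
                      _["score"] = best);
}
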