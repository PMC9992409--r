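#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward pass over a Plan7-like profile HMM with flanking insert
// states I0 / IL (free-insertion ends).  States: M0 (begin) .. ML, I0..IL,
// D1..DL, E.  Transition vectors are indexed 0..L (R passes length L+1);
// tMM[L] is M_L -> E, tIM[L] is I_L -> E, tDM[L] is D_L -> E.
// seq is 0-based residue indices into the 20-letter alphabet; -1 marks X
// (unknown), which emits with probability 1 under every state so it is
// neutral in the log-odds.
static double forward_loglik(const NumericMatrix& memis, // L x 20
                             const NumericVector& iemis, // 20
                             const NumericVector& tMM, const NumericVector& tMI,
                             const NumericVector& tMD, const NumericVector& tIM,
                             const NumericVector& tII, const NumericVector& tID,
                             const NumericVector& tDM, const NumericVector& tDI,
                             const NumericVector& tDD,
                             const IntegerVector& seq) {
  const int L = memis.nrow();
  const int n = seq.size();
  std::vector<double> fM(L + 1), fI(L + 1), fD(L + 1);
  std::vector<double> pM(L + 1), pI(L + 1), pD(L + 1);

  // i = 0: begin state, plus silent all-delete prefixes
  pM[0] = 1.0; pI[0] = 0.0; pD[0] = 0.0;
  for (int k = 1; k <= L; ++k) {
    pM[k] = 0.0; pI[k] = 0.0;
    pD[k] = pM[k - 1] * tMD[k - 1] + pD[k - 1] * tDD[k - 1];
  }

  double logscale = 0.0;
  for (int i = 1; i <= n; ++i) {
    const int a = seq[i - 1];
    // I0 (N-terminal flank) emits background
    double eI = (a < 0) ? 1.0 : iemis[a];
    fM[0] = 0.0; fD[0] = 0.0;
    fI[0] = eI * (pM[0] * tMI[0] + pI[0] * tII[0]);
    for (int k = 1; k <= L; ++k) {
      double eM = (a < 0) ? 1.0 : memis(k - 1, a);
      fM[k] = eM * (pM[k - 1] * tMM[k - 1] + pI[k - 1] * tIM[k - 1] +
                    pD[k - 1] * tDM[k - 1]);
      fI[k] = eI * (pM[k] * tMI[k] + pI[k] * tII[k] + pD[k] * tDI[k]);
      fD[k] = fM[k - 1] * tMD[k - 1] + fI[k - 1] * tID[k - 1] +
              fD[k - 1] * tDD[k - 1];
    }
    double s = 0.0;
    for (int k = 0; k <= L; ++k) s += fM[k] + fI[k] + fD[k];
    if (s <= 0.0) return R_NegInf;
    for (int k = 0; k <= L; ++k) {
      pM[k] = fM[k] / s; pI[k] = fI[k] / s; pD[k] = fD[k] / s;
    }
    logscale += std::log(s);
  }
  double term = pM[L] * tMM[L] + pI[L] * tIM[L] + pD[L] * tDM[L];
  if (term <= 0.0) return R_NegInf;
  return logscale + std::log(term);
}

// [[Rcpp::export]]
double cpp_forward_logodds(NumericMatrix match_emis, NumericVector ins_emis,
                           List trans, NumericVector background,
                           IntegerVector seq) {
  NumericVector tMM = trans["MM"], tMI = trans["MI"], tMD = trans["MD"];
  NumericVector tIM = trans["IM"], tII = trans["II"], tID = trans["ID"];
  NumericVector tDM = trans["DM"], tDI = trans["DI"], tDD = trans["DD"];
  double lp = forward_loglik(match_emis, ins_emis, tMM, tMI, tMD, tIM, tII,
                             tID, tDM, tDI, tDD, seq);
  // Null: identical state machine, every emission replaced by the background
  NumericMatrix bgm(match_emis.nrow(), 20);
  for (int k = 0; k < bgm.nrow(); ++k)
    for (int a = 0; a < 20; ++a) bgm(k, a) = background[a];
  double l0 = forward_loglik(bgm, background, tMM, tMI, tMD, tIM, tII, tID,
                             tDM, tDI, tDD, seq);
  return (lp - l0) / std::log(2.0);
}

// [[Rcpp::export]]
NumericVector cpp_forward_logodds_many(NumericMatrix match_emis,
                                       NumericVector ins_emis, List trans,
                                       NumericVector background, List seqs) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    out[i] = cpp_forward_logodds(match_emis, ins_emis, trans, background, s);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
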