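#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM forward and Viterbi dynamic programs, in log2 space.
//
// States: M_k (k = 1..L match states; M_0 is Begin, "M" at slot L means
// End), I_k (k = 0..L), D_k (k = 1..L). Transition tables are (L+1) x 3
// matrices: row k holds transitions out of {M_k, I_k, D_k} to destinations
// (M_{k+1}, I_k, D_{k+1}) in columns (0, 1, 2); invalid destinations carry
// -Inf. logEm is L x 4 (match emissions); logIns length 4 (insert
// emissions); query codes are 1..4, 0 = ambiguous (emits logAmb in both
// match and insert states so that the symbol is scored as background).

static const double NEG = -1e300;

static inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (b <= NEG / 2) return a;
  return a + std::log1p(std::exp2(b - a) * 1.0) / M_LN2;
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

static inline double emit(const NumericMatrix& logEm, int k, int code,
                          double logAmb) {
  return code == 0 ? logAmb : logEm(k - 1, code - 1);
}
static inline double iemit(const NumericVector& logIns, int code,
                           double logAmb) {
  return code == 0 ? logAmb : logIns[code - 1];
}

// [[Rcpp::export]]
double hmm_forward_log2(IntegerVector q, NumericMatrix logEm,
                        NumericMatrix tM, NumericMatrix tI, NumericMatrix tD,
                        NumericVector logIns, double logAmb) {
  const int L = logEm.nrow();
  const int n = q.size();
  std::vector<double> fM(L + 1, NEG), fI(L + 1, NEG), fD(L + 1, NEG);
  std::vector<double> nM(L + 1), nI(L + 1), nD(L + 1);

  fM[0] = 0.0;
  for (int k = 1; k <= L; ++k) {  // delete chain at i = 0
    fD[k] = lse3(fM[k - 1] + tM(k - 1, 2), fI[k - 1] + tI(k - 1, 2),
                 fD[k - 1] + tD(k - 1, 2));
  }
  for (int i = 1; i <= n; ++i) {
    const int code = q[i - 1];
    std::fill(nM.begin(), nM.end(), NEG);
    std::fill(nI.begin(), nI.end(), NEG);
    std::fill(nD.begin(), nD.end(), NEG);
    for (int k = 1; k <= L; ++k) {
      nM[k] = emit(logEm, k, code, logAmb) +
              lse3(fM[k - 1] + tM(k - 1, 0), fI[k - 1] + tI(k - 1, 0),
                   fD[k - 1] + tD(k - 1, 0));
    }
    for (int k = 0; k <= L; ++k) {
      nI[k] = iemit(logIns, code, logAmb) +
              lse3(fM[k] + tM(k, 1), fI[k] + tI(k, 1), fD[k] + tD(k, 1));
    }
    for (int k = 1; k <= L; ++k) {
      nD[k] = lse3(nM[k - 1] + tM(k - 1, 2), nI[k - 1] + tI(k - 1, 2),
                   nD[k - 1] + tD(k - 1, 2));
    }
    fM.swap(nM); fI.swap(nI); fD.swap(nD);
  }
  return lse3(fM[L] + tM(L, 0), fI[L] + tI(L, 0), fD[L] + tD(L, 0));
}

// Viterbi: returns matrix with one row per visited emitting/silent state on
// the best path (Begin/End excluded): columns (state, slot, qpos) with
// state 0=M, 1=I, 2=D; qpos = 1-based query position consumed (0 for D).
// [[Rcpp::export]]
List hmm_viterbi_path(IntegerVector q, NumericMatrix logEm,
                      NumericMatrix tM, NumericMatrix tI, NumericMatrix tD,
                      NumericVector logIns, double logAmb) {
  const int L = logEm.nrow();
  const int n = q.size();
  auto at = [L](int i, int k) { return i * (L + 1) + k; };
  std::vector<double> vM((n + 1) * (L + 1), NEG), vI = vM, vD = vM;
  std::vector<signed char> pM(vM.size(), -1), pI = pM, pD = pM;

  vM[at(0, 0)] = 0.0;
  for (int i = 0; i <= n; ++i) {
    if (i > 0) {
      const int code = q[i - 1];
      for (int k = 1; k <= L; ++k) {
        double a = vM[at(i - 1, k - 1)] + tM(k - 1, 0);
        double b = vI[at(i - 1, k - 1)] + tI(k - 1, 0);
        double c = vD[at(i - 1, k - 1)] + tD(k - 1, 0);
        double best = a; signed char p = 0;
        if (b > best) { best = b; p = 1; }
        if (c > best) { best = c; p = 2; }
        vM[at(i, k)] = best + emit(logEm, k, code, logAmb);
        pM[at(i, k)] = p;
      }
      for (int k = 0; k <= L; ++k) {
        double a = vM[at(i - 1, k)] + tM(k, 1);
        double b = vI[at(i - 1, k)] + tI(k, 1);
        double c = vD[at(i - 1, k)] + tD(k, 1);
        double best = a; signed char p = 0;
        if (b > best) { best = b; p = 1; }
        if (c > best) { best = c; p = 2; }
        vI[at(i, k)] = best + iemit(logIns, code, logAmb);
        pI[at(i, k)] = p;
      }
    }
    for (int k = 1; k <= L; ++k) {
      double a = vM[at(i, k - 1)] + tM(k - 1, 2);
      double b = vI[at(i, k - 1)] + tI(k - 1, 2);
      double c = vD[at(i, k - 1)] + tD(k - 1, 2);
      double best = a; signed char p = 0;
      if (b > best) { best = b; p = 1; }
      if (c > best) { best = c; p = 2; }
      if (best > vD[at(i, k)]) { vD[at(i, k)] = best; pD[at(i, k)] = p; }
    }
  }

  double a = vM[at(n, L)] + tM(L, 0);
  double b = vI[at(n, L)] + tI(L, 0);
  double c = vD[at(n, L)] + tD(L, 0);
  double best = a; int st = 0;
  if (b > best) { best = b; st = 1; }
  if (c > best) { best = c; st = 2; }

  std::vector<int> states, slots, qpos;
  int i = n, k = L;
  while (!(st == 0 && k == 0 && i == 0)) {
    signed char p;
    if (st == 0) {
      p = pM[at(i, k)];
      states.push_back(0); slots.push_back(k); qpos.push_back(i);
      --i; --k;
    } else if (st == 1) {
      p = pI[at(i, k)];
      states.push_back(1); slots.push_back(k); qpos.push_back(i);
      --i;
    } else {
      p = pD[at(i, k)];
      states.push_back(2); slots.push_back(k); qpos.push_back(0);
      --k;
    }
    st = p;
  }
  std::reverse(states.begin(), states.end());
  std::reverse(slots.begin(), slots.end());
  std::reverse(qpos.begin(), qpos.end());
  IntegerMatrix path(states.size(), 3);
  for (size_t r = 0; r < states.size(); ++r) {
    path(r, 0) = states[r]; path(r, 1) = slots[r]; path(r, 2) = qpos[r];
  }
  colnames(path) = CharacterVector::create("state", "slot", "qpos");
  return List::create(_["log2prob"] = best, _["path"] = path);
}
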