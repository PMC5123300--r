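#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap dynamic program over profile columns.
//
// S[i][j] is the (pre-computed) score of stacking column i of profile A on
// column j of profile B. Gap penalties are position-specific: consuming a
// column of A while gapping B costs gopen*occA[i] on opening and
// gext*occA[i] on extension (occ = non-gap occupancy of the consumed
// column), symmetrically for B. A gap of length k thus costs
// open + (k-1)*ext per unit occupancy.
//
// Returns the merge path as a vector of ops: 1 = consume one column of each
// (stack), 2 = consume A only (gap in B), 3 = consume B only (gap in A).
// Traceback tie-break: stack > gap-in-B > gap-in-A.
// [[Rcpp::export]]
IntegerVector profile_dp_path(NumericMatrix S, NumericVector occA,
                              NumericVector occB, double gopen, double gext) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e300;
  // state 0 = M (stack), 1 = X (consume A, gap in B), 2 = Y (consume B)
  std::vector<double> M((la + 1) * (lb + 1), NEG), X = M, Y = M;
  std::vector<signed char> pm(M.size(), -1), px = pm, py = pm;
  auto at = [lb](int i, int j) { return i * (lb + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    double enter = (i == 1 ? M[at(0, 0)] + gopen * occA[0]
                           : X[at(i - 1, 0)] + gext * occA[i - 1]);
    X[at(i, 0)] = enter;
    px[at(i, 0)] = (i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= lb; ++j) {
    double enter = (j == 1 ? M[at(0, 0)] + gopen * occB[0]
                           : Y[at(0, j - 1)] + gext * occB[j - 1]);
    Y[at(0, j)] = enter;
    py[at(0, j)] = (j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: stack A[i-1] with B[j-1]
      {
        double vm = M[at(i - 1, j - 1)], vx = X[at(i - 1, j - 1)],
               vy = Y[at(i - 1, j - 1)];
        double best = vm; signed char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        M[at(i, j)] = best + S(i - 1, j - 1);
        pm[at(i, j)] = p;
      }
      // X: consume A column i-1, gap in B
      {
        double vm = M[at(i - 1, j)] + gopen * occA[i - 1];
        double vx = X[at(i - 1, j)] + gext * occA[i - 1];
        double vy = Y[at(i - 1, j)] + gopen * occA[i - 1];
        double best = vm; signed char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        X[at(i, j)] = best;
        px[at(i, j)] = p;
      }
      // Y: consume B column j-1, gap in A
      {
        double vm = M[at(i, j - 1)] + gopen * occB[j - 1];
        double vx = X[at(i, j - 1)] + gopen * occB[j - 1];
        double vy = Y[at(i, j - 1)] + gext * occB[j - 1];
        double best = vm; signed char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        Y[at(i, j)] = best;
        py[at(i, j)] = p;
      }
    }
  }

  // choose final state, tie-break M > X > Y
  int st = 0;
  double best = M[at(la, lb)];
  if (X[at(la, lb)] > best) { best = X[at(la, lb)]; st = 1; }
  if (Y[at(la, lb)] > best) { best = Y[at(la, lb)]; st = 2; }

  std::vector<int> ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (st == 0) {
      signed char p = pm[at(i, j)];
      ops.push_back(1); --i; --j; st = p;
    } else if (st == 1) {
      signed char p = px[at(i, j)];
      ops.push_back(2); --i; st = p;
    } else {
      signed char p = py[at(i, j)];
      ops.push_back(3); --j; st = p;
    }
  }
  std::reverse(ops.begin(), ops.end());
  IntegerVector out(ops.begin(), ops.end());
  out.attr("score") = best;
  return out;
}
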