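#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Global (Needleman-Wunsch/Gotoh) profile-profile alignment with affine
// gaps.  A and B are nResidues x nCol frequency matrices; sub is the
// residue substitution matrix (same residue order).  A gap of length L
// costs open + L * ext.  Returns the column paths (0 = gap).
// [[Rcpp::export(name = ".pp_align")]]
List pp_align(NumericMatrix A, NumericMatrix B, NumericMatrix sub,
              double open, double ext) {
  int la = A.ncol(), lb = B.ncol(), nr = A.nrow();
  // precompute column-column expected scores
  NumericMatrix cs(la, lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < nr; ++a) {
        double fa = A(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < nr; ++b) {
          double fb = B(b, j);
          if (fb != 0.0) s += fa * fb * sub(a, b);
        }
      }
      cs(i, j) = s;
    }
  double first = -(open + ext);  // cost of the first residue of a gap
  // DP matrices: M diag, X gap in B (consume A), Y gap in A (consume B)
  NumericMatrix M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);
  IntegerMatrix tM(la + 1, lb + 1), tX(la + 1, lb + 1), tY(la + 1, lb + 1);
  for (int i = 0; i <= la; ++i)
    for (int j = 0; j <= lb; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= la; ++i) {
    X(i, 0) = first - ext * (i - 1);
    tX(i, 0) = (i == 1) ? 0 : 1;  // 0 from M, 1 extend
  }
  for (int j = 1; j <= lb; ++j) {
    Y(0, j) = first - ext * (j - 1);
    tY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double m0 = M(i - 1, j - 1), x0 = X(i - 1, j - 1), y0 = Y(i - 1, j - 1);
      double best = m0; int tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M(i, j) = best + cs(i - 1, j - 1);
      tM(i, j) = tb;
      double xo = M(i - 1, j) + first, xe = X(i - 1, j) - ext;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 0; }
      else { X(i, j) = xe; tX(i, j) = 1; }
      // gap in A: from M, from X (gap switch, re-open), or extend Y
      double yo = M(i, j - 1) + first, yx = X(i, j - 1) + first,
             ye = Y(i, j - 1) - ext;
      double yb = yo; int yt = 0;
      if (yx > yb) { yb = yx; yt = 1; }
      if (ye > yb) { yb = ye; yt = 2; }
      Y(i, j) = yb; tY(i, j) = yt;
    }
  }
  double sc = M(la, lb); int st = 0;
  if (X(la, lb) > sc) { sc = X(la, lb); st = 1; }
  if (Y(la, lb) > sc) { sc = Y(la, lb); st = 2; }
  // traceback
  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int prev = tM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; st = prev;
    } else if (st == 1) {
      int prev = tX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; st = (prev == 1) ? 1 : 0;
    } else {
      int prev = tY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; st = (prev == 2) ? 2 : (prev == 1 ? 1 : 0);
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Local (domain-anywhere) profile-HMM scoring.
// lem: L x 20 match emission log-odds (natural log, vs background);
// seq: 0-based residue indices, -1 for unknown (log-odds 0);
// transitions are natural-log probabilities, indexed by source state
// 1..L (row j-1).  Entry to any match state costs log(1/L); exit from any
// match state is free; flanking residues and insert emissions score 0
// (background).  Returns forward and Viterbi log-odds in nats.
// [[Rcpp::export(name = ".hmm_score_cpp")]]
List hmm_score_cpp(NumericMatrix lem, IntegerVector seq,
                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                   NumericVector tIM, NumericVector tII,
                   NumericVector tDM, NumericVector tDD) {
  int L = lem.nrow();
  int n = seq.size();
  if (n == 0)
    return List::create(_["forward"] = NEG_INF, _["viterbi"] = NEG_INF);
  // entry pays for a uniform prior over both the entry match state and the
  // domain start position; without the position term the forward sum over
  // ~n*L placements inflates scores of unrelated sequences
  double entry = -2.0 * std::log((double)L) - std::log((double)n + 1.0);
  std::vector<double> Mf(L + 1, NEG_INF), If(L + 1, NEG_INF),
      Df(L + 1, NEG_INF);
  std::vector<double> Mv(L + 1, NEG_INF), Iv(L + 1, NEG_INF),
      Dv(L + 1, NEG_INF);
  double total_f = NEG_INF, total_v = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    std::vector<double> Mf2(L + 1, NEG_INF), If2(L + 1, NEG_INF),
        Df2(L + 1, NEG_INF);
    std::vector<double> Mv2(L + 1, NEG_INF), Iv2(L + 1, NEG_INF),
        Dv2(L + 1, NEG_INF);
    int x = seq[i - 1];
    for (int j = 1; j <= L; ++j) {
      double em = (x >= 0) ? lem(j - 1, x) : 0.0;
      // forward
      double fin = entry;  // B at any time, flanks free
      if (j > 1) {
        fin = lse2(fin, Mf[j - 1] + tMM[j - 2]);
        fin = lse2(fin, If[j - 1] + tIM[j - 2]);
        fin = lse2(fin, Df[j - 1] + tDM[j - 2]);
      }
      Mf2[j] = em + fin;
      // viterbi
      double vin = entry;
      if (j > 1) {
        double a = Mv[j - 1] + tMM[j - 2];
        double b = Iv[j - 1] + tIM[j - 2];
        double c = Dv[j - 1] + tDM[j - 2];
        if (a > vin) vin = a;
        if (b > vin) vin = b;
        if (c > vin) vin = c;
      }
      Mv2[j] = em + vin;
      // insert states (emit at background, log-odds 0)
      If2[j] = lse2(Mf[j] + tMI[j - 1], If[j] + tII[j - 1]);
      double va = Mv[j] + tMI[j - 1], vb = Iv[j] + tII[j - 1];
      Iv2[j] = va > vb ? va : vb;
    }
    // delete states: within-position chain over j
    for (int j = 2; j <= L; ++j) {
      Df2[j] = lse2(Mf2[j - 1] + tMD[j - 2], Df2[j - 1] + tDD[j - 2]);
      double va = Mv2[j - 1] + tMD[j - 2], vb = Dv2[j - 1] + tDD[j - 2];
      Dv2[j] = va > vb ? va : vb;
    }
    for (int j = 1; j <= L; ++j) {
      total_f = lse2(total_f, Mf2[j]);  // exit free, trailing flank free
      if (Mv2[j] > total_v) total_v = Mv2[j];
    }
    Mf = Mf2; If = If2; Df = Df2;
    Mv = Mv2; Iv = Iv2; Dv = Dv2;
  }
  return List::create(_["forward"] = total_f, _["viterbi"] = total_v);
}

// Viterbi with traceback of the best-scoring domain window: returns the
// 0-based half-open range of sequence positions aligned to match/insert
// states on the optimal path.
// [[Rcpp::export(name = ".hmm_viterbi_range")]]
List hmm_viterbi_range(NumericMatrix lem, IntegerVector seq,
                       NumericVector tMM, NumericVector tMI,
                       NumericVector tMD, NumericVector tIM,
                       NumericVector tII, NumericVector tDM,
                       NumericVector tDD) {
  int L = lem.nrow(), n = seq.size();
  if (n == 0)
    return List::create(_["viterbi"] = NEG_INF, _["start"] = 0,
                        _["end"] = 0);
  double entry = -2.0 * std::log((double)L) - std::log((double)n + 1.0);
  // start[i][j] = sequence position where the domain alignment entered
  std::vector<double> Mv(L + 1, NEG_INF), Iv(L + 1, NEG_INF),
      Dv(L + 1, NEG_INF);
  std::vector<int> Ms(L + 1, -1), Is(L + 1, -1), Ds(L + 1, -1);
  double best = NEG_INF; int best_start = 0, best_end = 0;
  for (int i = 1; i <= n; ++i) {
    std::vector<double> Mv2(L + 1, NEG_INF), Iv2(L + 1, NEG_INF),
        Dv2(L + 1, NEG_INF);
    std::vector<int> Ms2(L + 1, -1), Is2(L + 1, -1), Ds2(L + 1, -1);
    int x = seq[i - 1];
    for (int j = 1; j <= L; ++j) {
      double em = (x >= 0) ? lem(j - 1, x) : 0.0;
      double vin = entry; int src = i - 1;  // fresh entry at this position
      if (j > 1) {
        double a = Mv[j - 1] + tMM[j - 2];
        double b = Iv[j - 1] + tIM[j - 2];
        double c = Dv[j - 1] + tDM[j - 2];
        if (a > vin) { vin = a; src = Ms[j - 1]; }
        if (b > vin) { vin = b; src = Is[j - 1]; }
        if (c > vin) { vin = c; src = Ds[j - 1]; }
      }
      Mv2[j] = em + vin; Ms2[j] = src;
      double va = Mv[j] + tMI[j - 1], vb = Iv[j] + tII[j - 1];
      if (va >= vb) { Iv2[j] = va; Is2[j] = Ms[j]; }
      else { Iv2[j] = vb; Is2[j] = Is[j]; }
    }
    for (int j = 2; j <= L; ++j) {
      double va = Mv2[j - 1] + tMD[j - 2], vb = Dv2[j - 1] + tDD[j - 2];
      if (va >= vb) { Dv2[j] = va; Ds2[j] = Ms2[j - 1]; }
      else { Dv2[j] = vb; Ds2[j] = Ds2[j - 1]; }
    }
    for (int j = 1; j <= L; ++j) {
      if (Mv2[j] > best) {
        best = Mv2[j];
        best_start = Ms2[j];  // 0-based: residues [best_start, i)
        best_end = i;
      }
    }
    Mv = Mv2; Iv = Iv2; Dv = Dv2;
    Ms = Ms2; Is = Is2; Ds = Ds2;
  }
  return List::create(_["viterbi"] = best, _["start"] = best_start,
                      _["end"] = best_end);
}
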