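#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment, Needleman-Wunsch (global) and
// Smith-Waterman (local).  Gap cost convention: a run of k gapped
// residues costs gap_open + k * gap_extend (BLAST-style 11/1 default).
//
// Three-state DP (Gotoh):
//   M[i][j]  best score ending with a[i] aligned to b[j]
//   X[i][j]  best score ending with a[i] aligned to a gap ("up")
//   Y[i][j]  best score ending with b[j] aligned to a gap ("left")
// Tie-breaking is fixed: diagonal (M) > up (X) > left (Y), both when
// choosing the predecessor state and when choosing the final state.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, NumericMatrix lut,
               double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const double ge = gap_extend;

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which state the max came from (0=M,1=X,2=Y,3=start/stop)
  std::vector<unsigned char> tM((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tX((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tY((n + 1) * (m + 1), 3);
  #define IDX(i, j) ((i) * (m + 1) + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = -(go + (i - 1) * ge);
    tX[IDX(i, 0)] = 1;
    if (local) { M[IDX(i, 0)] = 0.0; tM[IDX(i, 0)] = 3; }
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = -(go + (j - 1) * ge);
    tY[IDX(0, j)] = 2;
    if (local) { M[IDX(0, j)] = 0.0; tM[IDX(0, j)] = 3; }
  }

  for (int i = 1; i <= n; ++i) {
    int ai = a[i - 1] - 'A';
    for (int j = 1; j <= m; ++j) {
      double s = lut(ai, b[j - 1] - 'A');
      // M: diagonal move from best of M/X/Y at (i-1, j-1)
      double pm = M[IDX(i - 1, j - 1)], px = X[IDX(i - 1, j - 1)],
             py = Y[IDX(i - 1, j - 1)];
      double best = pm; unsigned char tb = 0;
      if (px > best) { best = px; tb = 1; }
      if (py > best) { best = py; tb = 2; }
      double mv = best + s;
      if (local && mv < 0.0) { mv = 0.0; tb = 3; }
      M[IDX(i, j)] = mv; tM[IDX(i, j)] = tb;
      // X: consume a[i], gap in b
      double xo = M[IDX(i - 1, j)] - go; double xy = Y[IDX(i - 1, j)] - go;
      if (xy > xo) xo = xy;  // allow Y->X gap switch at opening cost
      double xe = X[IDX(i - 1, j)] - ge;
      if (xo >= xe) {
        X[IDX(i, j)] = xo;
        tX[IDX(i, j)] = (M[IDX(i - 1, j)] >= Y[IDX(i - 1, j)]) ? 0 : 2;
      } else { X[IDX(i, j)] = xe; tX[IDX(i, j)] = 1; }
      // Y: consume b[j], gap in a
      double yo = M[IDX(i, j - 1)] - go; double yx = X[IDX(i, j - 1)] - go;
      if (yx > yo) yo = yx;  // allow X->Y gap switch at opening cost
      double ye = Y[IDX(i, j - 1)] - ge;
      if (yo >= ye) {
        Y[IDX(i, j)] = yo;
        tY[IDX(i, j)] = (M[IDX(i, j - 1)] >= X[IDX(i, j - 1)]) ? 0 : 1;
      } else { Y[IDX(i, j)] = ye; tY[IDX(i, j)] = 2; }
    }
  }

  // locate the alignment end
  int ei, ej; unsigned char est; double score;
  if (local) {
    score = 0.0; ei = 0; ej = 0; est = 3;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[IDX(i, j)] > score) { score = M[IDX(i, j)]; ei = i; ej = j; est = 0; }
  } else {
    ei = n; ej = m;
    score = M[IDX(n, m)]; est = 0;
    if (X[IDX(n, m)] > score) { score = X[IDX(n, m)]; est = 1; }
    if (Y[IDX(n, m)] > score) { score = Y[IDX(n, m)]; est = 2; }
    if (n == 0 && m == 0) { score = 0.0; est = 3; }
  }

  // traceback
  std::string ga, gb;
  int i = ei, j = ej; unsigned char st = est;
  while (i > 0 || j > 0) {
    if (st == 3) break;  // local alignment start
    if (st == 0) {
      // a zero-valued M cell in local mode is the (empty) alignment start
      if (local && M[IDX(i, j)] <= 0.0) break;
      unsigned char prev = tM[IDX(i, j)];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; st = (prev == 3) ? 3 : prev;
      if (local && st == 3) break;
    } else if (st == 1) {
      unsigned char prev = tX[IDX(i, j)];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; st = prev;
    } else {
      unsigned char prev = tY[IDX(i, j)];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  int ident = 0, len = ga.size();
  for (int k = 0; k < len; ++k) if (ga[k] == gb[k] && ga[k] != '-') ++ident;

  return List::create(
    _["score"] = score,
    _["aligned_a"] = ga, _["aligned_b"] = gb,
    _["a_start"] = i + 1, _["a_end"] = ei,
    _["b_start"] = j + 1, _["b_end"] = ej,
    _["identical"] = ident, _["length"] = len);
  #undef IDX
}

// Batched all-vs-all local alignment scores + stats used by the similarity
// network stage (avoids R-level call overhead for a few 10^4 pairs).
// Returns a data.frame-compatible list for pairs (qi, sj), qi != sj.
// [[Rcpp::export]]
List cpp_all_vs_all(std::vector<std::string> seqs, NumericMatrix lut,
                    double gap_open, double gap_extend) {
  int N = seqs.size();
  std::vector<int> qi, sj; std::vector<double> sc, ident, qcov, scov;
  for (int q = 0; q < N; ++q) {
    for (int s = 0; s < N; ++s) {
      if (q == s) continue;
      List r = cpp_align(seqs[q], seqs[s], lut, gap_open, gap_extend, true);
      double score = r["score"];
      int len = r["length"]; int idn = r["identical"];
      int a1 = r["a_start"], a2 = r["a_end"], b1 = r["b_start"], b2 = r["b_end"];
      qi.push_back(q + 1); sj.push_back(s + 1); sc.push_back(score);
      ident.push_back(len > 0 ? (double)idn / len : 0.0);
      qcov.push_back(len > 0 ? (double)(a2 - a1 + 1) / seqs[q].size() : 0.0);
      scov.push_back(len > 0 ? (double)(b2 - b1 + 1) / seqs[s].size() : 0.0);
    }
  }
  return List::create(_["query"] = qi, _["subject"] = sj, _["score"] = sc,
                      _["identity"] = ident, _["qcov"] = qcov, _["scov"] = scov);
}
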