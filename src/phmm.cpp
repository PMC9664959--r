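#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM Viterbi and forward scoring, glocal mode: every match/delete
// column is traversed; sequence flanks are absorbed by the terminal insert
// states I_0 and I_n.  State layout follows the classic plain profile HMM:
// nodes k = 0..n, with M_0 = begin, plus I_k and (k>=1) D_k; no I<->D
// transitions.  Transition row k holds, in order,
//   MM MI MD IM II DM DD
// i.e. M_k->M_{k+1}, M_k->I_k, M_k->D_{k+1}, I_k->M_{k+1}, I_k->I_k,
// D_k->M_{k+1}, D_k->D_{k+1}; at k=n the "M_{n+1}" target is the end state.
// Scores are log2-odds against an i.i.d. background null (no length term).

static const double NEG_INF = -1e300;

static inline double lse(double a, double b) {
  if (a <= NEG_INF / 2) return b;
  if (b <= NEG_INF / 2) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
List cpp_hmm_score(IntegerVector seq, NumericMatrix lem, NumericMatrix lei,
                   NumericMatrix ltr, bool want_path) {
  // lem: n x 20 match log-odds (natural log of em/bg); lei: (n+1) x 20
  // insert log-odds; ltr: (n+1) x 7 natural-log transition probabilities.
  const int n = lem.nrow(), L = seq.size();
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;
  #define ID(k, i) ((k) * (L + 1) + (i))
  std::vector<double> vM((n + 1) * (L + 1), NEG_INF), vI = vM, vD = vM;
  std::vector<double> fM = vM, fI = vM, fD = vM;
  std::vector<unsigned char> pM((n + 1) * (L + 1), 9), pI = pM, pD = pM;

  vM[ID(0, 0)] = 0.0; fM[ID(0, 0)] = 0.0;  // begin state
  for (int k = 0; k <= n; ++k) {
    for (int i = 0; i <= L; ++i) {
      if (k == 0 && i == 0) continue;
      // D_k (k>=1): from M_{k-1} or D_{k-1}, no emission
      if (k >= 1) {
        double a = vM[ID(k - 1, i)] + ltr(k - 1, MD);
        double c = vD[ID(k - 1, i)] + ltr(k - 1, DD);
        if (a >= c) { vD[ID(k, i)] = a; pD[ID(k, i)] = 0; }
        else        { vD[ID(k, i)] = c; pD[ID(k, i)] = 2; }
        fD[ID(k, i)] = lse(fM[ID(k - 1, i)] + ltr(k - 1, MD),
                           fD[ID(k - 1, i)] + ltr(k - 1, DD));
      }
      if (i >= 1) {
        int x = seq[i - 1];
        // M_k (k>=1): from M/I/D at node k-1, position i-1
        if (k >= 1) {
          double a = vM[ID(k - 1, i - 1)] + ltr(k - 1, MM);
          double c = vD[ID(k - 1, i - 1)] + ltr(k - 1, DM);
          double b = vI[ID(k - 1, i - 1)] + ltr(k - 1, IM);
          double best = a; unsigned char p = 0;           // tie-break M>D>I
          if (c > best) { best = c; p = 2; }
          if (b > best) { best = b; p = 1; }
          vM[ID(k, i)] = best + lem(k - 1, x); pM[ID(k, i)] = p;
          fM[ID(k, i)] = lem(k - 1, x) +
            lse(lse(fM[ID(k - 1, i - 1)] + ltr(k - 1, MM),
                    fI[ID(k - 1, i - 1)] + ltr(k - 1, IM)),
                fD[ID(k - 1, i - 1)] + ltr(k - 1, DM));
        }
        // I_k: from M_k or I_k at position i-1
        double a = vM[ID(k, i - 1)] + ltr(k, MI);
        double b = vI[ID(k, i - 1)] + ltr(k, II);
        if (a >= b) { vI[ID(k, i)] = a + lei(k, x); pI[ID(k, i)] = 0; }
        else        { vI[ID(k, i)] = b + lei(k, x); pI[ID(k, i)] = 1; }
        fI[ID(k, i)] = lei(k, x) + lse(fM[ID(k, i - 1)] + ltr(k, MI),
                                       fI[ID(k, i - 1)] + ltr(k, II));
      }
    }
  }
  // end state: from M_n, I_n, D_n
  double va = vM[ID(n, L)] + ltr(n, MM);
  double vc = vD[ID(n, L)] + ltr(n, DM);
  double vb = vI[ID(n, L)] + ltr(n, IM);
  double vit = va; unsigned char est = 0;
  if (vc > vit) { vit = vc; est = 2; }
  if (vb > vit) { vit = vb; est = 1; }
  double fwd = lse(lse(fM[ID(n, L)] + ltr(n, MM), fI[ID(n, L)] + ltr(n, IM)),
                   fD[ID(n, L)] + ltr(n, DM));

  CharacterVector path(0);
  if (want_path && vit > NEG_INF / 2) {
    std::vector<std::string> rev;
    int k = n, i = L; unsigned char st = est;
    while (!(k == 0 && i == 0)) {
      char lab = st == 0 ? 'M' : (st == 1 ? 'I' : 'D');
      rev.push_back(lab + std::to_string(k));
      unsigned char prev;
      if (st == 0) { prev = pM[ID(k, i)]; --k; --i; }
      else if (st == 1) { prev = pI[ID(k, i)]; --i; }
      else { prev = pD[ID(k, i)]; --k; }
      st = prev;
      if (k == 0 && i == 0) break;
    }
    path = CharacterVector(rev.size());
    for (size_t r = 0; r < rev.size(); ++r) path[r] = rev[rev.size() - 1 - r];
  }
  #undef ID
  const double LN2 = std::log(2.0);
  return List::create(_["viterbi"] = vit / LN2, _["forward"] = fwd / LN2,
                      _["path"] = path);
}
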