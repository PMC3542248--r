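#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Local alignment (Smith-Waterman, affine gaps) over integer-coded amino
// acid vectors. Gap of length L costs gapOpen + L * gapExt.

// score-only DP; returns best local score
static int sw_score(const int* a, int m, const int* b, int n,
                    const int* sub, int ncol, int gapOpen, int gapExt) {
  if (m == 0 || n == 0) return 0;
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  const int NEG = -1000000000;
  std::fill(E.begin(), E.end(), NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int* srow = sub + (size_t)a[i - 1] * ncol;
    int diag = 0;        // H[i-1][0]
    int F = NEG;
    for (int j = 1; j <= n; ++j) {
      int up = H[j];     // H[i-1][j]
      int e = E[j] - gapExt;
      int eo = up - gapOpen - gapExt;
      if (eo > e) e = eo;
      E[j] = e;
      int f = F - gapExt;
      int fo = H[j - 1] - gapOpen - gapExt;
      if (fo > f) f = fo;
      F = f;
      int h = diag + srow[b[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[j] = h;
      diag = up;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_one")]]
int sw_score_one(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gapOpen, int gapExt) {
  return sw_score(a.begin(), a.size(), b.begin(), b.size(),
                  sub.begin(), sub.nrow(), gapOpen, gapExt);
}

// Best raw score over all query-frame x subject-frame combinations for
// every query-subject transcript pair. qframes/sframes: concatenated
// integer-coded frame translations with index vectors giving, for each
// transcript, the 6 frame slots (offsets into the concatenated vector).
//
// Returns a DataFrame with one row per pair whose best raw score reached
// minRaw: qi, si (1-based transcript indices), qframe, sframe (1..6) and
// raw score. Pairs where qids[qi] == sids[si] are skipped (intra-set use).
// [[Rcpp::export(name = ".sw_best_hits")]]
DataFrame sw_best_hits(IntegerVector seqQ, IntegerVector offQ, IntegerVector lenQ,
                       IntegerVector seqS, IntegerVector offS, IntegerVector lenS,
                       int nq, int ns,
                       CharacterVector qids, CharacterVector sids,
                       IntegerMatrix sub, int gapOpen, int gapExt,
                       double minRaw) {
  std::vector<int> rqi, rsi, rqf, rsf, rraw;
  const int* SQ = seqQ.begin();
  const int* SS = seqS.begin();
  const int* subp = sub.begin();
  int ncol = sub.nrow();
  for (int qi = 0; qi < nq; ++qi) {
    for (int si = 0; si < ns; ++si) {
      if (qids[qi] == sids[si]) continue;
      int best = -1, bqf = 0, bsf = 0;
      for (int qf = 0; qf < 6; ++qf) {
        int qslot = qi * 6 + qf;
        int mlen = lenQ[qslot];
        if (mlen == 0) continue;
        const int* a = SQ + offQ[qslot];
        for (int sf = 0; sf < 6; ++sf) {
          int sslot = si * 6 + sf;
          int nlen = lenS[sslot];
          if (nlen == 0) continue;
          int sc = sw_score(a, mlen, SS + offS[sslot], nlen,
                            subp, ncol, gapOpen, gapExt);
          if (sc > best) { best = sc; bqf = qf + 1; bsf = sf + 1; }
        }
      }
      if (best >= minRaw && best > 0) {
        rqi.push_back(qi + 1);
        rsi.push_back(si + 1);
        rqf.push_back(bqf);
        rsf.push_back(bsf);
        rraw.push_back(best);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["qi"] = rqi, _["si"] = rsi,
                           _["qframe"] = rqf, _["sframe"] = rsf,
                           _["raw"] = rraw);
}

// Full DP with traceback for one pair: returns score, alignment columns
// and identical columns of the best local alignment.
// [[Rcpp::export(name = ".sw_align_stats")]]
IntegerVector sw_align_stats(IntegerVector av, IntegerVector bv,
                             IntegerMatrix sub, int gapOpen, int gapExt) {
  int m = av.size(), n = bv.size();
  const int* a = av.begin();
  const int* b = bv.begin();
  const int* subp = sub.begin();
  int ncol = sub.nrow();
  const int NEG = -1000000000;
  // full matrices (pairs reaching this path are few)
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  // trace: for H, 0 = stop, 1 = diag, 2 = from E (gap in b), 3 = from F;
  // for E/F, 1 = opened here, 0 = extended
  std::vector<unsigned char> tH((m + 1) * (n + 1), 0),
      tE((m + 1) * (n + 1), 0), tF((m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* srow = subp + (size_t)a[i - 1] * ncol;
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t)i * (n + 1) + j;
      size_t up = c - (n + 1), left = c - 1, dg = up - 1;
      int e = E[up] - gapExt, eo = H[up] - gapOpen - gapExt;
      if (eo >= e) { E[c] = eo; tE[c] = 1; } else { E[c] = e; tE[c] = 0; }
      int f = F[left] - gapExt, fo = H[left] - gapOpen - gapExt;
      if (fo >= f) { F[c] = fo; tF[c] = 1; } else { F[c] = f; tF[c] = 0; }
      int h = H[dg] + srow[b[j - 1]];
      unsigned char t = 1;
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[c] = h; tH[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int cols = 0, ident = 0;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char t = tH[c];
      if (t == 0) break;
      if (t == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++ident;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {      // gap in b: consume a[i]
      ++cols;
      unsigned char t = tE[c];
      --i;
      if (t == 1) state = 0;
    } else {                      // gap in a: consume b[j]
      ++cols;
      unsigned char t = tF[c];
      --j;
      if (t == 1) state = 0;
    }
  }
  return IntegerVector::create(_["score"] = best, _["columns"] = cols,
                               _["matches"] = ident);
}
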