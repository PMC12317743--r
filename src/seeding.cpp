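#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Multi-order subsequence seeding.
//
// For each length-n window the seed under order i (pivot index i) is the
// length-k subsequence minimizing (psi, -omega). The i-1 characters left of
// the pivot are scored pivot-outward with the reverse tables, the k-i
// characters right of it with the forward tables. Two families of DP tables
// are filled per pivot candidate q:
//
//   R[p][j][v]: min/max omega over selections of j characters from
//               window[p..q-1], part indices assigned leftward from the
//               pivot (the newly added, leftmost character gets index j),
//               with running psi residue v.
//   F[p][j][v]: the mirror image over window[q+1..p].
//
// Omega updates multiply by +/-1 signs, so both the minimum and the maximum
// must be carried: a sign flip exchanges which extreme can win later. All
// omega arithmetic is exact in doubles (|omega| <= (k+1)*2^40 < 2^53).
//
// Tie handling: each extreme additionally carries the base-S code (window
// order, big-endian) of the lexicographically smallest part string
// achieving it, and a flag marking whether two *distinct* strings achieve
// the extreme. Outward extension prepends a common character, so the
// lex-min propagates compositionally. The winning seed string is decoded
// from the composite code (no positional traceback); its position tuple is
// the greedy leftmost embedding, which is the lex-smallest tuple spelling
// it. Records where a distinct-string tie touches the optimum are flagged
// so the caller can re-resolve them against the enumeration oracle.

static inline int idx3(int l, int j, int s, int k, int d) {
  return l + k * (j + d * s);
}
static inline int idx2(int l, int s, int k) { return l + k * s; }

struct Ext {
  double val;
  uint64_t code; // lex-min achieving part string, window order, big-endian
  bool amb;      // >= 2 distinct strings achieve val
};

struct Cell {
  Ext mn, mx;
  bool ex;
};

struct DPBuf {
  std::vector<Cell> c;
  int k, d;
  void resize(int stages, int k_, int d_) {
    k = k_; d = d_;
    size_t sz = (size_t)stages * k * d;
    if (c.size() < sz) c.resize(sz);
  }
  inline size_t st(int stage, int j, int v) const {
    return ((size_t)stage * k + j) * d + v;
  }
};

// merge candidate extreme into accumulator (minimization)
static inline void merge_min(Ext &acc, bool &has, const Ext &cand) {
  if (!has || cand.val < acc.val) { acc = cand; has = true; }
  else if (cand.val == acc.val) {
    acc.amb = acc.amb || cand.amb || (cand.code != acc.code);
    if (cand.code < acc.code) acc.code = cand.code;
  }
}
static inline void merge_max(Ext &acc, bool &has, const Ext &cand) {
  if (!has || cand.val > acc.val) { acc = cand; has = true; }
  else if (cand.val == acc.val) {
    acc.amb = acc.amb || cand.amb || (cand.code != acc.code);
    if (cand.code < acc.code) acc.code = cand.code;
  }
}

// one outward DP step: predecessor cell extended by character c at part
// index j (tables already selected); updates cur from prev-take
static inline void take_step(const Cell &pv, Cell &cur, bool &hasmn,
                             bool &hasmx, double b1, double ab2,
                             uint64_t cpow, int c_sym) {
  // new omega = prev * b1 + ab2 ; b1 = +/-1 swaps which extreme feeds which
  const Ext &lo = (b1 > 0) ? pv.mn : pv.mx;
  const Ext &hi = (b1 > 0) ? pv.mx : pv.mn;
  Ext nmn{lo.val * b1 + ab2, cpow * (uint64_t)c_sym + lo.code, lo.amb};
  Ext nmx{hi.val * b1 + ab2, cpow * (uint64_t)c_sym + hi.code, hi.amb};
  merge_min(cur.mn, hasmn, nmn);
  merge_max(cur.mx, hasmx, nmx);
}

// reverse-part DP for pivot q; stages p = 0..q (stage p covers [p, q-1])
static void rev_dp(const int *x, int q, int k, int d, int S,
                   const double *AR, const double *BR1, const double *BR2,
                   const int *CR, const uint64_t *Spow, DPBuf &B) {
  B.resize(q + 1, k, d);
  for (int j = 0; j < k; ++j)
    for (int v = 0; v < d; ++v) B.c[B.st(q, j, v)].ex = false;
  Cell &base = B.c[B.st(q, 0, 0)];
  base.ex = true;
  base.mn = Ext{0.0, 0, false};
  base.mx = Ext{0.0, 0, false};
  for (int p = q - 1; p >= 0; --p) {
    int c = x[p];
    int jmax = std::min(k - 1, q - p);
    for (int j = 0; j <= jmax; ++j) {
      for (int v = 0; v < d; ++v) {
        Cell cur;
        cur.ex = false;
        bool hasmn = false, hasmx = false;
        const Cell &sk = B.c[B.st(p + 1, j, v)];
        if (sk.ex) {
          merge_min(cur.mn, hasmn, sk.mn);
          merge_max(cur.mx, hasmx, sk.mx);
        }
        if (j >= 1) {
          int vprev = v - CR[idx2(j - 1, c, k)];
          if (vprev < 0) vprev += d;
          const Cell &pv = B.c[B.st(p + 1, j - 1, vprev)];
          if (pv.ex) {
            double b1 = BR1[idx3(j - 1, v, c, k, d)];
            double ab2 = AR[idx3(j - 1, v, c, k, d)] *
                         BR2[idx3(j - 1, v, c, k, d)];
            take_step(pv, cur, hasmn, hasmx, b1, ab2, Spow[j - 1], c);
          }
        }
        cur.ex = hasmn;
        B.c[B.st(p, j, v)] = cur;
      }
    }
    for (int j = jmax + 1; j < k; ++j)
      for (int v = 0; v < d; ++v) B.c[B.st(p, j, v)].ex = false;
  }
}

// forward-part DP for pivot q; stages s = p - q, p = q..n-1 ([q+1, p])
static void fwd_dp(const int *x, int q, int n, int k, int d, int S,
                   const double *AF, const double *BF1, const double *BF2,
                   const int *CF, const uint64_t *Spow, DPBuf &B) {
  B.resize(n - q, k, d);
  for (int j = 0; j < k; ++j)
    for (int v = 0; v < d; ++v) B.c[B.st(0, j, v)].ex = false;
  Cell &base = B.c[B.st(0, 0, 0)];
  base.ex = true;
  base.mn = Ext{0.0, 0, false};
  base.mx = Ext{0.0, 0, false};
  for (int p = q + 1; p <= n - 1; ++p) {
    int s = p - q, c = x[p];
    int jmax = std::min(k - 1, p - q);
    for (int j = 0; j <= jmax; ++j) {
      for (int v = 0; v < d; ++v) {
        Cell cur;
        cur.ex = false;
        bool hasmn = false, hasmx = false;
        const Cell &sk = B.c[B.st(s - 1, j, v)];
        if (sk.ex) {
          merge_min(cur.mn, hasmn, sk.mn);
          merge_max(cur.mx, hasmx, sk.mx);
        }
        if (j >= 1) {
          int vprev = v - CF[idx2(j - 1, c, k)];
          if (vprev < 0) vprev += d;
          const Cell &pv = B.c[B.st(s - 1, j - 1, vprev)];
          if (pv.ex) {
            double b1 = BF1[idx3(j - 1, v, c, k, d)];
            double ab2 = AF[idx3(j - 1, v, c, k, d)] *
                         BF2[idx3(j - 1, v, c, k, d)];
            // forward part: the new character is the rightmost chosen, but
            // its part index j is the largest, i.e. in window order it is
            // appended at the END: code = prev_code * S + c
            const Ext &lo = (b1 > 0) ? pv.mn : pv.mx;
            const Ext &hi = (b1 > 0) ? pv.mx : pv.mn;
            Ext nmn{lo.val * b1 + ab2, lo.code * (uint64_t)S + (uint64_t)c,
                    lo.amb};
            Ext nmx{hi.val * b1 + ab2, hi.code * (uint64_t)S + (uint64_t)c,
                    hi.amb};
            merge_min(cur.mn, hasmn, nmn);
            merge_max(cur.mx, hasmx, nmx);
          }
        }
        cur.ex = hasmn;
        B.c[B.st(s, j, v)] = cur;
      }
    }
    for (int j = jmax + 1; j < k; ++j)
      for (int v = 0; v < d; ++v) B.c[B.st(s, j, v)].ex = false;
  }
}

// [[Rcpp::export]]
List cpp_seed_sequence(IntegerVector xsym, int n, int t, int k, int d,
                       NumericVector AF, NumericVector BF1, NumericVector BF2,
                       IntegerVector CF,
                       NumericVector AR, NumericVector BR1, NumericVector BR2,
                       IntegerVector CR,
                       NumericVector AP, NumericVector BP1, NumericVector BP2,
                       IntegerVector CP,
                       CharacterVector alphabet) {
  int N = xsym.size();
  int S = alphabet.size();
  std::vector<int> out_w, out_order, out_pivot;
  std::vector<double> out_psi, out_omega;
  std::vector<int> out_pos;
  std::vector<bool> out_tie;
  std::vector<std::string> out_seed;
  int skipped = 0;
  if (N >= n) {
    std::vector<std::string> alpha(S);
    for (int s = 0; s < S; ++s) alpha[s] = as<std::string>(alphabet[s]);

    const double *pAF = AF.begin(), *pBF1 = BF1.begin(), *pBF2 = BF2.begin();
    const double *pAR = AR.begin(), *pBR1 = BR1.begin(), *pBR2 = BR2.begin();
    const double *pAP = AP.begin(), *pBP1 = BP1.begin(), *pBP2 = BP2.begin();
    const int *pCF = CF.begin(), *pCR = CR.begin(), *pCP = CP.begin();

    std::vector<uint64_t> Spow(k + 2);
    Spow[0] = 1;
    for (int j = 1; j <= k + 1; ++j) Spow[j] = Spow[j - 1] * (uint64_t)S;

    // boundary slices per pivot q (values at the full part region)
    size_t slice_sz = (size_t)n * k * d;
    std::vector<Cell> Lsl(slice_sz), Fsl(slice_sz);
    auto sl = [&](int q, int j, int v) {
      return ((size_t)q * k + j) * d + v;
    };

    DPBuf buf;
    std::vector<int> win(n), canpos(k);

    for (int w = 0; w + n <= N; ++w) {
      bool bad = false;
      for (int p = 0; p < n; ++p) {
        win[p] = xsym[w + p];
        if (win[p] < 0) bad = true;
      }
      if (bad) { ++skipped; continue; }

      for (int q = 0; q < n; ++q) {
        rev_dp(win.data(), q, k, d, S, pAR, pBR1, pBR2, pCR, Spow.data(),
               buf);
        for (int j = 0; j < k; ++j)
          for (int v = 0; v < d; ++v)
            Lsl[sl(q, j, v)] = buf.c[buf.st(0, j, v)];
        fwd_dp(win.data(), q, n, k, d, S, pAF, pBF1, pBF2, pCF, Spow.data(),
               buf);
        for (int j = 0; j < k; ++j)
          for (int v = 0; v < d; ++v)
            Fsl[sl(q, j, v)] = buf.c[buf.st(n - 1 - q, j, v)];
      }

      for (int i = 1; i <= t; ++i) {
        int jL = i - 1, jR = k - i;
        bool found = false, tie = false;
        int bestPsi = 0;
        double bestOmega = 0.0;
        uint64_t bestCode = 0;
        for (int q = jL; q <= n - 1 - jR; ++q) {
          int c = win[q];
          double b1 = pBP1[idx2(i - 1, c, k)], b2 = pBP2[idx2(i - 1, c, k)];
          double a = pAP[idx2(i - 1, c, k)];
          int cp = pCP[idx2(i - 1, c, k)];
          for (int vL = 0; vL < d; ++vL) {
            const Cell &L = Lsl[sl(q, jL, vL)];
            if (!L.ex) continue;
            const Ext &eR = (b1 > 0) ? L.mx : L.mn;
            for (int vR = 0; vR < d; ++vR) {
              const Cell &F = Fsl[sl(q, jR, vR)];
              if (!F.ex) continue;
              const Ext &eF = (b2 > 0) ? F.mx : F.mn;
              int psi = (vL + cp + vR) % d;
              double omega = eR.val * b1 + a + eF.val * b2;
              uint64_t comp = eR.code * Spow[jR + 1] +
                              (uint64_t)c * Spow[jR] + eF.code;
              bool camb = eR.amb || eF.amb;
              if (!found || psi < bestPsi ||
                  (psi == bestPsi && omega > bestOmega)) {
                found = true;
                bestPsi = psi; bestOmega = omega; bestCode = comp;
                tie = camb;
              } else if (psi == bestPsi && omega == bestOmega) {
                tie = tie || camb || (comp != bestCode);
                if (comp < bestCode) bestCode = comp;
              }
            }
          }
        }
        if (!found) stop("internal error: no feasible pivot for an order");

        // decode the winning string and re-embed greedily (lex-min tuple)
        std::string seed(k, ' ');
        uint64_t code = bestCode;
        std::vector<int> symz(k);
        for (int j = k - 1; j >= 0; --j) {
          symz[j] = (int)(code % (uint64_t)S);
          code /= (uint64_t)S;
        }
        for (int j = 0; j < k; ++j) seed[j] = alpha[symz[j]][0];
        int p = 0;
        for (int j = 0; j < k; ++j) {
          while (win[p] != symz[j]) ++p;
          canpos[j] = p;
          ++p;
        }

        out_w.push_back(w);
        out_order.push_back(i);
        out_pivot.push_back(canpos[i - 1]);
        out_psi.push_back((double)bestPsi);
        out_omega.push_back(bestOmega);
        out_seed.push_back(seed);
        out_tie.push_back(tie);
        for (int j = 0; j < k; ++j) out_pos.push_back(canpos[j]);
      }
    }
  }

  int nr = out_w.size();
  IntegerMatrix posm(nr, k);
  for (int r = 0; r < nr; ++r)
    for (int j = 0; j < k; ++j) posm(r, j) = out_pos[(size_t)r * k + j];
  return List::create(_["window"] = wrap(out_w),
                      _["order"] = wrap(out_order),
                      _["pivot"] = wrap(out_pivot),
                      _["psi"] = wrap(out_psi),
                      _["omega"] = wrap(out_omega),
                      _["seed"] = wrap(out_seed),
                      _["tie"] = wrap(out_tie),
                      _["positions"] = posm,
                      _["skipped"] = skipped);
}
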