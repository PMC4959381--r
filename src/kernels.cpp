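#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Residue codes 0..23 cover the 24-letter amino-acid alphabet; code 24 is the
// internal padding sentinel.  All kernels receive the substitution table as a
// 25x25 integer matrix whose sentinel row/column is a large negative constant,
// so padded cells can never contribute a positive alignment score.

static const int SENTINEL = 24;

// Affine-gap local alignment recurrences with zero-clamped H and unclamped
// E/F, initial values H(i,0)=H(0,j)=E(i,0)=F(0,j)=0.  A gap of length g costs
// alpha + (g-1)*beta.

// [[Rcpp::export]]
List cpp_sw_full(IntegerVector q, IntegerVector s, IntegerMatrix sbt,
                 int alpha, int beta) {
  const int m = q.size(), n = s.size();
  IntegerMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int e = std::max(H(i, j - 1) - alpha, E(i, j - 1) - beta);
      const int f = std::max(H(i - 1, j) - alpha, F(i - 1, j) - beta);
      const int d = H(i - 1, j - 1) + sbt(q[i - 1], s[j - 1]);
      int h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      if (d > h) h = d;
      H(i, j) = h; E(i, j) = e; F(i, j) = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return List::create(_["score"] = best, _["best_i"] = bi, _["best_j"] = bj,
                      _["H"] = H, _["E"] = E, _["F"] = F);
}

// Linear-space score-only scan; optionally carries the exact-match-count
// companion recurrences (N_A/N_E/N_F) so that the identity count at the
// maximum-score cell is available without traceback.  Branch precedence for
// the companion values: zero-stop, then diagonal, then E (gap-open before
// gap-extend), then F.  The running best uses strict improvement, so the
// first row-major argmax wins.

// [[Rcpp::export]]
List cpp_sw_linear(IntegerVector q, IntegerVector s, IntegerMatrix sbt,
                   int alpha, int beta, bool with_nid) {
  const int m = q.size(), n = s.size();
  std::vector<int> H(n + 1, 0), F(n + 1, 0), NA_(n + 1, 0), NF(n + 1, 0);
  int best = 0, bi = 0, bj = 0, bnid = 0;
  for (int i = 1; i <= m; ++i) {
    int hdiag = 0, e = 0, ne = 0, nadiag = 0;
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int holdj = H[j];          // H(i-1, j)
      e = std::max(H[j - 1] - alpha, e - beta);   // H[j-1] already row i
      const int f = std::max(holdj - alpha, F[j] - beta);
      const int sc = sbt(qi, s[j - 1]);
      const int d = hdiag + sc;
      int h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      if (d > h) h = d;
      int na = 0, nf = 0;
      if (with_nid) {
        const int ne_new = (j == 1) ? 0
          : (e == H[j - 1] - alpha ? NA_[j - 1] : ne);
        nf = (i == 1) ? 0 : (f == holdj - alpha ? NA_[j] : NF[j]);
        if (h != 0) {
          if (h == d)      na = nadiag + (qi == s[j - 1] ? 1 : 0);
          else if (h == e) na = ne_new;
          else             na = nf;
        }
        ne = ne_new;
        nadiag = NA_[j];
        NA_[j] = na; NF[j] = nf;
      }
      hdiag = holdj;
      H[j] = h; F[j] = f;
      if (h > best) { best = h; bi = i; bj = j; bnid = na; }
    }
  }
  return List::create(_["score"] = best, _["best_i"] = bi, _["best_j"] = bj,
                      _["nid"] = bnid);
}

// Lane-parallel pass over a packed subject batch.  `cols` is (maxlen x L)
// with columns[p,k] the (p+1)-th residue code of lane k (sentinel beyond the
// lane's length).  Per subject position two gather tables are built first:
// sprofile[p][r][k] = sbt(r, cols[p,k]) and mprofile[p][r][k] = 1 iff
// r == cols[p,k]; every DP step then reads a whole 16-wide row of each.
// The pass processes query rows [i_offset+1 .. i_offset+len(qchunk)] and
// carries the boundary state (last H row, last F row, companion rows when
// nid is requested, and the per-lane running best) so that a long query can
// be split into consecutive chunks with results identical to a single pass.

// [[Rcpp::export]]
List cpp_lane_pass(IntegerVector qchunk, int i_offset, IntegerMatrix cols,
                   IntegerMatrix sbt, int alpha, int beta, bool with_nid,
                   IntegerMatrix Hrow, IntegerMatrix Frow,
                   IntegerMatrix NArow, IntegerMatrix NFrow,
                   IntegerVector best_score, IntegerVector best_i,
                   IntegerVector best_j, IntegerVector best_nid) {
  const int maxlen = cols.nrow(), L = cols.ncol();
  const int nrows = qchunk.size();

  // gather profiles: layout p-major, then residue, then lane
  std::vector<int32_t> sprof((size_t)maxlen * 24 * L);
  std::vector<uint8_t> mprof(with_nid ? (size_t)maxlen * 24 * L : 0);
  for (int p = 0; p < maxlen; ++p) {
    for (int r = 0; r < 24; ++r) {
      int32_t *sp = &sprof[((size_t)p * 24 + r) * L];
      for (int k = 0; k < L; ++k) sp[k] = sbt(r, cols(p, k));
      if (with_nid) {
        uint8_t *mp = &mprof[((size_t)p * 24 + r) * L];
        for (int k = 0; k < L; ++k) mp[k] = (cols(p, k) == r) ? 1 : 0;
      }
    }
  }

  // working copies of the carried rows, lane-major per column: X[p*L + k]
  std::vector<int> H((size_t)(maxlen + 1) * L), F((size_t)(maxlen + 1) * L),
                   NA_((size_t)(maxlen + 1) * L), NF((size_t)(maxlen + 1) * L);
  for (int p = 0; p <= maxlen; ++p)
    for (int k = 0; k < L; ++k) {
      H[(size_t)p * L + k] = Hrow(k, p);
      F[(size_t)p * L + k] = Frow(k, p);
      if (with_nid) {
        NA_[(size_t)p * L + k] = NArow(k, p);
        NF[(size_t)p * L + k] = NFrow(k, p);
      }
    }

  std::vector<int> best(best_score.begin(), best_score.end());
  std::vector<int> bi(best_i.begin(), best_i.end());
  std::vector<int> bj(best_j.begin(), best_j.end());
  std::vector<int> bn(best_nid.begin(), best_nid.end());
  std::vector<int> hdiag(L), e(L), ne(L), nadiag(L);

  for (int r = 0; r < nrows; ++r) {
    const int qi = qchunk[r];
    const int i_global = i_offset + r + 1;
    for (int k = 0; k < L; ++k) {
      hdiag[k] = H[k];            // column 0 (always 0)
      e[k] = 0; ne[k] = 0; nadiag[k] = NA_[k];
    }
    for (int p = 1; p <= maxlen; ++p) {
      int *Hp = &H[(size_t)p * L], *Hpm1 = &H[(size_t)(p - 1) * L];
      int *Fp = &F[(size_t)p * L];
      const int32_t *sp = &sprof[((size_t)(p - 1) * 24 + qi) * L];
      const uint8_t *mp = with_nid ? &mprof[((size_t)(p - 1) * 24 + qi) * L]
                                   : (const uint8_t *)0;
      int *NAp = &NA_[(size_t)p * L], *NApm1 = &NA_[(size_t)(p - 1) * L];
      int *NFp = &NF[(size_t)p * L];
      for (int k = 0; k < L; ++k) {
        const int holdj = Hp[k];
        const int ek = std::max(Hpm1[k] - alpha, e[k] - beta);
        const int fk = std::max(holdj - alpha, Fp[k] - beta);
        const int dk = hdiag[k] + sp[k];
        int h = 0;
        if (ek > h) h = ek;
        if (fk > h) h = fk;
        if (dk > h) h = dk;
        int na = 0;
        if (with_nid) {
          const int ne_new = (p == 1) ? 0
            : (ek == Hpm1[k] - alpha ? NApm1[k] : ne[k]);
          const int nf = (i_global == 1) ? 0
            : (fk == holdj - alpha ? NAp[k] : NFp[k]);
          if (h != 0) {
            if (h == dk)      na = nadiag[k] + mp[k];
            else if (h == ek) na = ne_new;
            else              na = nf;
          }
          ne[k] = ne_new;
          nadiag[k] = NAp[k];
          NAp[k] = na; NFp[k] = nf;
        }
        hdiag[k] = holdj;
        Hp[k] = h; Fp[k] = fk; e[k] = ek;
        if (h > best[k]) {
          best[k] = h; bi[k] = i_global; bj[k] = p; bn[k] = na;
        }
      }
    }
  }

  IntegerMatrix Hout(L, maxlen + 1), Fout(L, maxlen + 1),
                NAout(L, maxlen + 1), NFout(L, maxlen + 1);
  for (int p = 0; p <= maxlen; ++p)
    for (int k = 0; k < L; ++k) {
      Hout(k, p) = H[(size_t)p * L + k];
      Fout(k, p) = F[(size_t)p * L + k];
      if (with_nid) {
        NAout(k, p) = NA_[(size_t)p * L + k];
        NFout(k, p) = NF[(size_t)p * L + k];
      }
    }
  return List::create(_["Hrow"] = Hout, _["Frow"] = Fout,
                      _["NArow"] = NAout, _["NFrow"] = NFout,
                      _["best_score"] = IntegerVector(best.begin(), best.end()),
                      _["best_i"] = IntegerVector(bi.begin(), bi.end()),
                      _["best_j"] = IntegerVector(bj.begin(), bj.end()),
                      _["best_nid"] = IntegerVector(bn.begin(), bn.end()));
}
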