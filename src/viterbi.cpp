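#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Glocal Viterbi over a nucleotide profile HMM: global with respect to the
// traversed stretch of the model (entry/exit may be internal match states,
// paying the entry/exit log-probabilities supplied by the caller), local
// with respect to the read (flanking read sequence outside the hit is free,
// i.e. emitted at background with log-odds 0).
//
// All scores are log2-odds against the background distribution. Ambiguity
// codes (anything outside ACGT, case-insensitive) emit at background.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// trans columns: 0 mm, 1 mi, 2 md, 3 im, 4 ii, 5 id, 6 dm, 7 dd, 8 di
// row k (0-based) holds transitions out of model node k+1, k+1 = 1..K-1.
// mlo: K x 4 match log-odds; ilo rows 0..K-2 are the insert states sitting
// after match nodes 1..K-1.

struct PhmmFlat {
  int K;
  std::vector<double> mlo, ilo;                       // K x 5 (col 4 = 0)
  std::vector<double> mm, mi, md, im, ii, id, dm, dd, di;
  std::vector<double> entry, exitp;
  PhmmFlat(const NumericMatrix &mloR, const NumericMatrix &iloR,
           const NumericMatrix &tr, const NumericVector &entryR,
           const NumericVector &exitpR) {
    K = mloR.nrow();
    mlo.assign((size_t) K * 5, 0.0);
    ilo.assign((size_t) K * 5, 0.0);
    for (int j = 0; j < K; ++j)
      for (int c = 0; c < 4; ++c) {
        mlo[(size_t) j * 5 + c] = mloR(j, c);
        if (j < iloR.nrow()) ilo[(size_t) j * 5 + c] = iloR(j, c);
      }
    const int T = tr.nrow();
    mm.resize(T); mi.resize(T); md.resize(T);
    im.resize(T); ii.resize(T); id.resize(T);
    dm.resize(T); dd.resize(T); di.resize(T);
    for (int k = 0; k < T; ++k) {
      mm[k] = tr(k, 0); mi[k] = tr(k, 1); md[k] = tr(k, 2);
      im[k] = tr(k, 3); ii[k] = tr(k, 4); id[k] = tr(k, 5);
      dm[k] = tr(k, 6); dd[k] = tr(k, 7); di[k] = tr(k, 8);
    }
    entry.assign(entryR.begin(), entryR.end());
    exitp.assign(exitpR.begin(), exitpR.end());
  }
};

struct VitHit {
  double score;
  int read_start, read_end, model_start, model_end;
};

// Row-major DP over (i = read position, j = model node), with traceback.
// tb* codes: M: 0 entry, 1 from M, 2 from I, 3 from D;
//            I: 0 from M, 1 from I, 2 from D; D: 0 from M, 1 from D, 2 from I.
static VitHit viterbi_core(const PhmmFlat &P, const std::string &seq,
                           std::vector<signed char> *pathM,
                           std::vector<signed char> *pathI,
                           std::vector<signed char> *pathD) {
  const int K = P.K;
  const int L = (int) seq.size();
  const double NEG = -1e300;
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) x[i] = base_code(seq[i]);

  const size_t row = (size_t) K;
  std::vector<double> Mp(row, NEG), Ip(row, NEG), Dp(row, NEG);
  std::vector<double> Mc(row), Ic(row), Dc(row);
  std::vector<signed char> &tbM = *pathM, &tbI = *pathI, &tbD = *pathD;
  tbM.assign((size_t) (L + 1) * K, -1);
  tbI.assign((size_t) (L + 1) * K, -1);
  tbD.assign((size_t) (L + 1) * K, -1);

  double best = NEG;
  int bi = -1, bj = -1;

  for (int i = 1; i <= L; ++i) {
    const int c = x[i - 1];
    const size_t off = (size_t) i * K;
    for (int j = 0; j < K; ++j) {
      const double em = (c < 4) ? P.mlo[(size_t) j * 5 + c] : 0.0;
      double bm = P.entry[j];
      signed char cm = 0;
      if (j > 0) {
        const int k = j - 1;
        double v = Mp[k] + P.mm[k];
        if (v > bm) { bm = v; cm = 1; }
        v = Ip[k] + P.im[k];
        if (v > bm) { bm = v; cm = 2; }
        v = Dp[k] + P.dm[k];
        if (v > bm) { bm = v; cm = 3; }
      }
      Mc[j] = em + bm;
      tbM[off + j] = cm;

      if (j < K - 1) {
        const double iem = (c < 4) ? P.ilo[(size_t) j * 5 + c] : 0.0;
        double b2 = Mp[j] + P.mi[j];
        signed char c2 = 0;
        double v = Ip[j] + P.ii[j];
        if (v > b2) { b2 = v; c2 = 1; }
        v = Dp[j] + P.di[j];
        if (v > b2) { b2 = v; c2 = 2; }
        Ic[j] = iem + b2;
        tbI[off + j] = c2;
      } else Ic[j] = NEG;

      if (j > 0) {
        const int k = j - 1;
        double b3 = Mc[k] + P.md[k];
        signed char c3 = 0;
        double v = Dc[k] + P.dd[k];
        if (v > b3) { b3 = v; c3 = 1; }
        v = Ic[k] + P.id[k];
        if (v > b3) { b3 = v; c3 = 2; }
        Dc[j] = b3;
        tbD[off + j] = c3;
      } else Dc[j] = NEG;

      const double ex = Mc[j] + P.exitp[j];
      if (ex > best) { best = ex; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  VitHit h;
  h.score = best;
  h.read_end = bi;
  h.model_end = bj + 1;
  // traceback for the start coordinates
  int i = bi, j = bj;
  char st = 'M';
  while (true) {
    const size_t off = (size_t) i * K;
    if (st == 'M') {
      const signed char cc = tbM[off + j];
      if (cc == 0) break;
      st = (cc == 1) ? 'M' : (cc == 2) ? 'I' : 'D';
      --i; --j;
    } else if (st == 'I') {
      const signed char cc = tbI[off + j];
      st = (cc == 0) ? 'M' : (cc == 1) ? 'I' : 'D';
      --i;
    } else {
      const signed char cc = tbD[off + j];
      st = (cc == 0) ? 'M' : (cc == 1) ? 'D' : 'I';
      --j;
    }
  }
  h.read_start = i;
  h.model_start = j + 1;
  return h;
}

// [[Rcpp::export]]
List viterbi_glocal_cpp(NumericMatrix mlo, NumericMatrix ilo,
                        NumericMatrix trans, NumericVector entry,
                        NumericVector exitp, std::string seq) {
  if (seq.size() < 1) stop("sequence must have length >= 1");
  PhmmFlat P(mlo, ilo, trans, entry, exitp);
  std::vector<signed char> tbM, tbI, tbD;
  VitHit h = viterbi_core(P, seq, &tbM, &tbI, &tbD);

  // rebuild the full state path from the traceback
  const int K = P.K;
  std::vector<std::string> path;
  int i = h.read_end, j = h.model_end - 1;
  char st = 'M';
  while (true) {
    path.push_back(std::string(1, st) + std::to_string(j + 1));
    const size_t off = (size_t) i * K;
    if (st == 'M') {
      const signed char cc = tbM[off + j];
      if (cc == 0) break;
      st = (cc == 1) ? 'M' : (cc == 2) ? 'I' : 'D';
      --i; --j;
    } else if (st == 'I') {
      const signed char cc = tbI[off + j];
      st = (cc == 0) ? 'M' : (cc == 1) ? 'I' : 'D';
      --i;
    } else {
      const signed char cc = tbD[off + j];
      st = (cc == 0) ? 'M' : (cc == 1) ? 'D' : 'I';
      --j;
    }
  }
  std::reverse(path.begin(), path.end());

  return List::create(_["bit_score"] = h.score,
                      _["read_start"] = h.read_start,
                      _["read_end"] = h.read_end,
                      _["model_start"] = h.model_start,
                      _["model_end"] = h.model_end,
                      _["path"] = wrap(path));
}

// Batch variant used by search(): one row of score/coordinates per read.
// [[Rcpp::export]]
DataFrame viterbi_batch_cpp(NumericMatrix mlo, NumericMatrix ilo,
                            NumericMatrix trans, NumericVector entry,
                            NumericVector exitp, CharacterVector seqs) {
  PhmmFlat P(mlo, ilo, trans, entry, exitp);
  const int n = seqs.size();
  NumericVector sc(n);
  IntegerVector rs(n), re(n), ms(n), me(n);
  std::vector<signed char> tbM, tbI, tbD;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    if (s.size() < 1) stop("sequence must have length >= 1");
    VitHit h = viterbi_core(P, s, &tbM, &tbI, &tbD);
    sc[r] = h.score;
    rs[r] = h.read_start;
    re[r] = h.read_end;
    ms[r] = h.model_start;
    me[r] = h.model_end;
  }
  return DataFrame::create(_["bit_score"] = sc,
                           _["read_start"] = rs, _["read_end"] = re,
                           _["model_start"] = ms, _["model_end"] = me);
}
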