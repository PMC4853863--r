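// Affine-gap pairwise alignment kernels (Gotoh three-state recursion).
//
// Conventions, fixed package-wide:
//  - a gap run of length L costs gap_open + L * gap_extend (the first gap
//    residue pays open + extend);
//  - global alignment penalizes end gaps;
//  - traceback tie-breaking prefers diagonal over up (gap in b) over left
//    (gap in a), and within a state prefers the M predecessor, then X, then Y;
//  - percent identity: identical columns / all alignment columns (global),
//    identical columns / aligned columns (local).
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// char -> alphabet index lookup built from the scoring-matrix alphabet
static void build_lookup(const std::string& alphabet, int* lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
}

static std::vector<int> encode(const std::string& s, const int* lut,
                               const std::string& alphabet) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0)
      stop("invalid-input: character '%s' not in alphabet '%s'",
           std::string(1, s[i]).c_str(), alphabet.c_str());
    v[i] = code;
  }
  return v;
}

// traceback state codes
enum { ST_M = 0, ST_X = 1, ST_Y = 2, ST_START = 3 };  // X: gap in b, Y: gap in a

// max of (m, x, y) with preference M > X > Y on ties
static inline int argmax3(double m, double x, double y, double& best) {
  best = m; int st = ST_M;
  if (x > best) { best = x; st = ST_X; }
  if (y > best) { best = y; st = ST_Y; }
  return st;
}

// flatten Rcpp matrix to row-major C array for cache-friendly row access
static std::vector<double> flatten_rowmajor(const NumericMatrix& S) {
  const int K = S.nrow();
  std::vector<double> M((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) M[(size_t)r * K + c] = S(r, c);
  return M;
}

static double sw_score_only(const std::vector<int>& A, const std::vector<int>& B,
                            const std::vector<double>& SM, int K,
                            double go, double ge);

struct AlnOut {
  double score;
  std::string aligned_a, aligned_b;
  int n_identical, n_columns;
  int a_start, a_end, b_start, b_end;  // 1-based; 0 when empty (local)
};

// ---------------------------------------------------------------- global ---
// Rolling-row Gotoh; packed direction byte per cell (bits 0-1: M predecessor,
// 2-3: X predecessor, 4-5: Y predecessor) kept only when traceback is needed.
static AlnOut nw_core(const std::vector<int>& A, const std::vector<int>& B,
                      const std::string& a, const std::string& b,
                      const NumericMatrix& S, double go, double ge,
                      bool traceback) {
  const std::vector<double> SM = flatten_rowmajor(S);
  const int n = (int)A.size(), m = (int)B.size();
  const size_t w = (size_t)m + 1;
  const double NI = -1e30;  // effective -inf, safe under subtraction
  std::vector<double> Mp(w), Xp(w), Yp(w), Mc(w), Xc(w), Yc(w);
  std::vector<uint8_t> dir;
  if (traceback) dir.assign((size_t)(n + 1) * w, 0);
  Mp[0] = 0.0; Xp[0] = NI; Yp[0] = NI;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NI; Xp[j] = NI; Yp[j] = -(go + ge * j);
    if (traceback) dir[j] = (uint8_t)(((j == 1) ? ST_M : ST_Y) << 4);
  }
  const int nrowS = S.nrow();
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NI; Xc[0] = -(go + ge * i); Yc[0] = NI;
    if (traceback) dir[(size_t)i * w] = (uint8_t)(((i == 1) ? ST_M : ST_X) << 2);
    const double* Srow = &SM[(size_t)A[i - 1] * nrowS];
    uint8_t* drow = traceback ? &dir[(size_t)i * w] : NULL;
    for (int j = 1; j <= m; ++j) {
      double best;
      int stM = argmax3(Mp[j - 1], Xp[j - 1], Yp[j - 1], best);
      const double mc = best + Srow[B[j - 1]];
      int stX = argmax3(Mp[j] - go - ge, Xp[j] - ge, Yp[j] - go - ge, best);
      const double xc = best;
      int stY = argmax3(Mc[j - 1] - go - ge, Xc[j - 1] - go - ge,
                        Yc[j - 1] - ge, best);
      Mc[j] = mc; Xc[j] = xc; Yc[j] = best;
      if (traceback)
        drow[j] = (uint8_t)(stM | (stX << 2) | (stY << 4));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  AlnOut out;
  double best;
  int st = argmax3(Mp[m], Xp[m], Yp[m], best);
  out.score = best;
  out.n_identical = 0;
  out.n_columns = 0;
  out.a_start = n ? 1 : 0; out.a_end = n;
  out.b_start = m ? 1 : 0; out.b_end = m;
  if (!traceback) return out;
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t dby = dir[(size_t)i * w + j];
    if (st == ST_M) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (A[i - 1] == B[j - 1]) ++out.n_identical;
      st = dby & 3; --i; --j;
    } else if (st == ST_X) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      st = (dby >> 2) & 3; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      st = (dby >> 4) & 3; --j;
    }
    ++out.n_columns;
  }
  out.aligned_a.assign(ra.rbegin(), ra.rend());
  out.aligned_b.assign(rb.rbegin(), rb.rend());
  return out;
}

// ----------------------------------------------------------------- local ---
// Rolling-row local Gotoh; packed direction byte (bits 0-1: H predecessor or
// ST_START, 2-3: X, 4-5: Y).
static AlnOut sw_core(const std::vector<int>& A, const std::vector<int>& B,
                      const std::string& a, const std::string& b,
                      const NumericMatrix& S, double go, double ge,
                      bool traceback) {
  const std::vector<double> SM = flatten_rowmajor(S);
  const int n = (int)A.size(), m = (int)B.size();
  const size_t w = (size_t)m + 1;
  const double NI = -1e30;
  std::vector<double> Hp(w, 0.0), Xp(w, NI), Yp(w, NI), Hc(w), Xc(w), Yc(w);
  std::vector<uint8_t> dir;
  if (traceback) dir.assign((size_t)(n + 1) * w, (uint8_t)ST_START);
  double best_score = 0.0;
  int bi = 0, bj = 0;
  const int nrowS = S.nrow();
  for (int i = 1; i <= n; ++i) {
    Hc[0] = 0.0; Xc[0] = NI; Yc[0] = NI;
    const double* Srow = &SM[(size_t)A[i - 1] * nrowS];
    uint8_t* drow = traceback ? &dir[(size_t)i * w] : NULL;
    for (int j = 1; j <= m; ++j) {
      double best;
      int stH = argmax3(Hp[j - 1], Xp[j - 1], Yp[j - 1], best);
      double h = best + Srow[B[j - 1]];
      if (stH == ST_M && Hp[j - 1] == 0.0) stH = ST_START;  // fresh start
      if (h <= 0.0) { h = 0.0; stH = ST_START; }
      int stX = argmax3(Hp[j] - go - ge, Xp[j] - ge, Yp[j] - go - ge, best);
      const double xc = best;
      int stY = argmax3(Hc[j - 1] - go - ge, Xc[j - 1] - go - ge,
                        Yc[j - 1] - ge, best);
      Hc[j] = h; Xc[j] = xc; Yc[j] = best;
      if (traceback)
        drow[j] = (uint8_t)(stH | (stX << 2) | (stY << 4));
      if (h > best_score) { best_score = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  AlnOut out;
  out.score = best_score;
  out.n_identical = 0; out.n_columns = 0;
  out.a_start = out.a_end = out.b_start = out.b_end = 0;
  if (best_score <= 0.0) { out.score = 0.0; return out; }
  if (!traceback) return out;
  std::string ra, rb;
  int i = bi, j = bj;
  out.a_end = bi; out.b_end = bj;
  int st = ST_M;
  while (i > 0 && j > 0) {
    const uint8_t dby = dir[(size_t)i * w + j];
    if (st == ST_M) {
      const int p = dby & 3;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (A[i - 1] == B[j - 1]) ++out.n_identical;
      ++out.n_columns;
      --i; --j;
      if (p == ST_START) break;
      st = p;
    } else if (st == ST_X) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      ++out.n_columns;
      st = (dby >> 2) & 3; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      ++out.n_columns;
      st = (dby >> 4) & 3; --j;
    }
  }
  out.a_start = i + 1;
  out.b_start = j + 1;
  out.aligned_a.assign(ra.rbegin(), ra.rend());
  out.aligned_b.assign(rb.rbegin(), rb.rend());
  return out;
}

static List aln_to_list(const AlnOut& o) {
  return List::create(
      _["score"] = o.score, _["aligned_a"] = o.aligned_a,
      _["aligned_b"] = o.aligned_b, _["n_identical"] = o.n_identical,
      _["n_columns"] = o.n_columns, _["a_start"] = o.a_start,
      _["a_end"] = o.a_end, _["b_start"] = o.b_start, _["b_end"] = o.b_end);
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, NumericMatrix smat,
                  std::string alphabet, double gap_open, double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  std::vector<int> A = encode(a, lut, alphabet), B = encode(b, lut, alphabet);
  return aln_to_list(nw_core(A, B, a, b, smat, gap_open, gap_extend, true));
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, NumericMatrix smat,
                  std::string alphabet, double gap_open, double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  std::vector<int> A = encode(a, lut, alphabet), B = encode(b, lut, alphabet);
  return aln_to_list(sw_core(A, B, a, b, smat, gap_open, gap_extend, true));
}

// Global alignment of many pairs; returns score, n_identical, n_columns.
// [[Rcpp::export]]
NumericMatrix cpp_nw_batch(CharacterVector seqs_a, CharacterVector seqs_b,
                           NumericMatrix smat, std::string alphabet,
                           double gap_open, double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  const int n = seqs_a.size();
  if (seqs_b.size() != n) stop("invalid-input: length mismatch");
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("score", "n_identical", "n_columns");
  for (int r = 0; r < n; ++r) {
    std::string a = as<std::string>(seqs_a(r)), b = as<std::string>(seqs_b(r));
    std::vector<int> A = encode(a, lut, alphabet), B = encode(b, lut, alphabet);
    AlnOut o = nw_core(A, B, a, b, smat, gap_open, gap_extend, true);
    out(r, 0) = o.score; out(r, 1) = o.n_identical; out(r, 2) = o.n_columns;
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Local-alignment scores (no traceback) for 1-based index pairs (ai, bi)
// into the two sequence sets; used by the reciprocal-best-hit search.
// [[Rcpp::export]]
NumericVector cpp_sw_score_batch(CharacterVector seqs_a, CharacterVector seqs_b,
                                 IntegerVector ai, IntegerVector bi,
                                 NumericMatrix smat, std::string alphabet,
                                 double gap_open, double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  const int na = seqs_a.size(), nb = seqs_b.size(), np = ai.size();
  if (bi.size() != np) stop("invalid-input: index length mismatch");
  std::vector<std::string> sa(na), sb(nb);
  std::vector<std::vector<int>> ea(na), eb(nb);
  for (int i = 0; i < na; ++i) { sa[i] = as<std::string>(seqs_a(i)); ea[i] = encode(sa[i], lut, alphabet); }
  for (int i = 0; i < nb; ++i) { sb[i] = as<std::string>(seqs_b(i)); eb[i] = encode(sb[i], lut, alphabet); }
  NumericVector out(np);
  const std::vector<double> SM = flatten_rowmajor(smat);
  for (int r = 0; r < np; ++r) {
    int i = ai[r] - 1, j = bi[r] - 1;
    if (i < 0 || i >= na || j < 0 || j >= nb)
      stop("invalid-input: index out of range");
    out[r] = sw_score_only(ea[i], eb[j], SM, smat.nrow(), gap_open, gap_extend);
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Fast score-only local alignment (rolling single row, no traceback).
static double sw_score_only(const std::vector<int>& A, const std::vector<int>& B,
                            const std::vector<double>& SM, int K,
                            double go, double ge) {
  const int n = (int)A.size(), m = (int)B.size();
  const double NI = -1e30;
  const double goe = go + ge;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NI);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* Srow = &SM[(size_t)A[i] * K];
    double f = NI, hdiag = H[0];
    for (int j = 1; j <= m; ++j) {
      double e = E[j];
      double h = hdiag + Srow[B[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
      const double ho = h - goe;
      e -= ge;
      E[j] = (ho > e) ? ho : e;
      f -= ge;
      if (ho > f) f = ho;
    }
  }
  return best;
}

// Full local-alignment statistics for 1-based index pairs (traceback, no
// alignment strings): score, identical and total aligned columns, aligned
// residue counts of each member (for coverage filters), percent identity.
// [[Rcpp::export]]
NumericMatrix cpp_sw_stats_batch(CharacterVector seqs_a, CharacterVector seqs_b,
                                 IntegerVector ai, IntegerVector bi,
                                 NumericMatrix smat, std::string alphabet,
                                 double gap_open, double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  const int na = seqs_a.size(), nb = seqs_b.size(), np = ai.size();
  if (bi.size() != np) stop("invalid-input: index length mismatch");
  std::vector<std::string> sa(na), sb(nb);
  std::vector<std::vector<int>> ea(na), eb(nb);
  for (int i = 0; i < na; ++i) { sa[i] = as<std::string>(seqs_a(i)); ea[i] = encode(sa[i], lut, alphabet); }
  for (int i = 0; i < nb; ++i) { sb[i] = as<std::string>(seqs_b(i)); eb[i] = encode(sb[i], lut, alphabet); }
  NumericMatrix out(np, 6);
  colnames(out) = CharacterVector::create("score", "n_identical", "n_columns",
                                          "alen_a", "alen_b", "pid");
  for (int r = 0; r < np; ++r) {
    int i = ai[r] - 1, j = bi[r] - 1;
    if (i < 0 || i >= na || j < 0 || j >= nb)
      stop("invalid-input: index out of range");
    AlnOut o = sw_core(ea[i], eb[j], sa[i], sb[j], smat, gap_open, gap_extend,
                       true);
    out(r, 0) = o.score;
    out(r, 1) = o.n_identical;
    out(r, 2) = o.n_columns;
    out(r, 3) = o.a_end > 0 ? o.a_end - o.a_start + 1 : 0;
    out(r, 4) = o.b_end > 0 ? o.b_end - o.b_start + 1 : 0;
    out(r, 5) = o.n_columns > 0 ? 100.0 * o.n_identical / o.n_columns : 0.0;
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ------------------------------------------------- brute-force oracles -----
// Exhaustive enumeration of every global alignment (move sequence), scoring
// affine gap runs incrementally.  Exponential; intended for sequences <= ~8.
static void bf_rec(const std::vector<int>& A, const std::vector<int>& B, int i,
                   int j, int last, double acc, const NumericMatrix& S,
                   double go, double ge, double& best) {
  const int n = (int)A.size(), m = (int)B.size();
  if (i == n && j == m) {
    if (acc > best) best = acc;
    return;
  }
  if (i < n && j < m)
    bf_rec(A, B, i + 1, j + 1, ST_M, acc + S(A[i], B[j]), S, go, ge, best);
  if (i < n)
    bf_rec(A, B, i + 1, j, ST_X, acc - ge - (last == ST_X ? 0.0 : go), S, go,
           ge, best);
  if (j < m)
    bf_rec(A, B, i, j + 1, ST_Y, acc - ge - (last == ST_Y ? 0.0 : go), S, go,
           ge, best);
}

// [[Rcpp::export]]
double cpp_bf_global_score(std::string a, std::string b, NumericMatrix smat,
                           std::string alphabet, double gap_open,
                           double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  std::vector<int> A = encode(a, lut, alphabet), B = encode(b, lut, alphabet);
  double best = NEG_INF;
  bf_rec(A, B, 0, 0, -1, 0.0, smat, gap_open, gap_extend, best);
  return best;
}

// Local oracle: max over all non-empty substring pairs of the global oracle,
// floored at 0 (the empty alignment).
// [[Rcpp::export]]
double cpp_bf_local_score(std::string a, std::string b, NumericMatrix smat,
                          std::string alphabet, double gap_open,
                          double gap_extend) {
  int lut[256];
  build_lookup(alphabet, lut);
  std::vector<int> A = encode(a, lut, alphabet), B = encode(b, lut, alphabet);
  const int n = (int)A.size(), m = (int)B.size();
  double best = 0.0;
  for (int i1 = 0; i1 < n; ++i1)
    for (int i2 = i1 + 1; i2 <= n; ++i2)
      for (int j1 = 0; j1 < m; ++j1)
        for (int j2 = j1 + 1; j2 <= m; ++j2) {
          std::vector<int> suba(A.begin() + i1, A.begin() + i2);
          std::vector<int> subb(B.begin() + j1, B.begin() + j2);
          double s = NEG_INF;
          bf_rec(suba, subb, 0, 0, -1, 0.0, smat, gap_open, gap_extend, s);
          if (s > best) best = s;
        }
  return best;
}

// ----------------------------------------------------- k-mer prefilter -----
// Sparse counts of distinct shared k-mers between two protein sets.  Returns
// a data frame (i, j, shared) of nonzero entries, 1-based indices.
// [[Rcpp::export]]
DataFrame cpp_kmer_shared(CharacterVector seqs_a, CharacterVector seqs_b,
                          int k, std::string alphabet) {
  if (k < 1 || k > 6) stop("invalid-config: k must be in 1..6");
  int lut[256];
  build_lookup(alphabet, lut);
  const int na = seqs_a.size(), nb = seqs_b.size();
  const uint64_t width = alphabet.size();
  std::unordered_map<uint64_t, std::vector<int>> index;  // kmer -> subjects
  for (int j = 0; j < nb; ++j) {
    std::string s = as<std::string>(seqs_b(j));
    std::vector<int> e = encode(s, lut, alphabet);
    if ((int)e.size() < k) continue;
    for (size_t p = 0; p + k <= e.size(); ++p) {
      uint64_t key = 0;
      for (int q = 0; q < k; ++q) key = key * width + e[p + q];
      auto& v = index[key];
      if (v.empty() || v.back() != j) v.push_back(j);
    }
  }
  std::vector<int> ri, rj, rc;
  std::vector<int> cnt(nb, 0);
  std::vector<int> touched;
  for (int i = 0; i < na; ++i) {
    std::string s = as<std::string>(seqs_a(i));
    std::vector<int> e = encode(s, lut, alphabet);
    if ((int)e.size() < k) continue;
    std::vector<uint64_t> keys;
    keys.reserve(e.size());
    for (size_t p = 0; p + k <= e.size(); ++p) {
      uint64_t key = 0;
      for (int q = 0; q < k; ++q) key = key * width + e[p + q];
      keys.push_back(key);
    }
    std::sort(keys.begin(), keys.end());
    keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
    touched.clear();
    for (uint64_t key : keys) {
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (int j : it->second) {
        if (cnt[j] == 0) touched.push_back(j);
        ++cnt[j];
      }
    }
    std::sort(touched.begin(), touched.end());
    for (int j : touched) {
      ri.push_back(i + 1); rj.push_back(j + 1); rc.push_back(cnt[j]);
      cnt[j] = 0;
    }
  }
  return DataFrame::create(_["i"] = ri, _["j"] = rj, _["shared"] = rc);
}
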