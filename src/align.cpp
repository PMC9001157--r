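// Pairwise nucleotide alignment core: Needleman-Wunsch / Gotoh global and
// Smith-Waterman local alignment with affine gaps and deterministic
// tie-breaking (prefer diagonal, then up, then left during traceback).
//
// Conventions, fixed by the package contract:
//   * alphabet A,C,G,T,N after uppercasing; N scores as a mismatch against
//     everything, including another N (masked positions are not evidence);
//   * a gap run of length k costs gap_open + (k-1) * gap_extend
//     (so gap_open == gap_extend gives linear gap costs);
//   * local alignment footprints are 0-based half-open on each input;
//     on equal maxima the earliest cell (smallest end row, then column) wins.
//
// The fill keeps only two rows of each score matrix and a packed one-byte
// traceback per cell (2 bits per state), so the cell loop stays in cache.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("non-IUPAC character '%s' in sequence", std::string(1, s[i]).c_str());
    v[i] = c;
  }
  return v;
}

// purines A(0), G(2); pyrimidines C(1), T(3): transition iff same parity
static inline bool is_transition(int x, int y) { return (x & 1) == (y & 1); }

struct AlnCounts {
  int score, n_match, n_mismatch, n_columns, n_valid, n_ts, n_tv;
  std::string aln_a, aln_b;
  int a_start, a_end, b_start, b_end;
};

// traceback state codes; SSTOP marks a local-alignment start cell
enum { SM = 0, SX = 1, SY = 2, SSTOP = 3 };
static inline unsigned char pack(int pm, int px, int py) {
  return (unsigned char)(pm | (px << 2) | (py << 4));
}
static inline int get_pm(unsigned char t) { return t & 3; }
static inline int get_px(unsigned char t) { return (t >> 2) & 3; }
static inline int get_py(unsigned char t) { return (t >> 4) & 3; }

// scratch buffers reused across calls in one batch
struct Work {
  std::vector<int> Mp, Xp, Yp, Mc, Xc, Yc;
  std::vector<unsigned char> tb;
};

// accumulate one traceback column into the counts
static inline void tally(AlnCounts& out, int x, int y) {
  ++out.n_columns;
  if (x == y && x != 4) ++out.n_match; else ++out.n_mismatch;
  if (x != 4 && y != 4) {
    ++out.n_valid;
    if (x != y) { if (is_transition(x, y)) ++out.n_ts; else ++out.n_tv; }
  }
}

static AlnCounts gotoh_global(const std::vector<int>& a, const std::vector<int>& b,
                              int match, int mismatch, int go, int ge,
                              Work& w, bool want_strings,
                              const std::string* sa = nullptr, const std::string* sb = nullptr) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  // interleaved rows [M, X, Y] per cell: one cache stream instead of three
  w.Mp.assign(3 * W, NEG);
  w.Mc.assign(3 * W, NEG);
  w.tb.resize((size_t)(n + 1) * W);
  int* prev = w.Mp.data();
  int* cur = w.Mc.data();
  // substitution lookup: s[x*5 + y]
  int sub[25];
  for (int x = 0; x < 5; ++x)
    for (int y = 0; y < 5; ++y)
      sub[x * 5 + y] = (x == y && x != 4) ? match : mismatch;
  // row 0: only Y (gaps in a) is reachable
  prev[0] = 0;
  w.tb[0] = 0;
  for (int j = 1; j <= m; ++j) {
    prev[3 * j + 2] = go + (j - 1) * ge;
    w.tb[j] = pack(SM, SM, j == 1 ? SM : SY);
  }
  for (int i = 1; i <= n; ++i) {
    unsigned char* trow = &w.tb[(size_t)i * W];
    const int* srow = &sub[a[i - 1] * 5];
    const int* bp = b.data();
    // column 0: only X (gaps in b) reachable
    cur[0] = NEG; cur[2] = NEG;
    cur[1] = go + (i - 1) * ge;
    trow[0] = pack(SM, i == 1 ? SM : SX, SM);
    int ycM = cur[0], ycX = cur[1], ycY = cur[2]; // current row, previous column
    for (int j = 1; j <= m; ++j) {
      const int* d = prev + 3 * (j - 1);  // diagonal predecessor
      const int* u = d + 3;               // vertical predecessor
      const int s = srow[bp[j - 1]];
      // M from diagonal; preference M > X > Y on ties
      const int bm = d[0], bx = d[1], by = d[2];
      const int dmax = bm >= bx ? (bm >= by ? bm : by) : (bx >= by ? bx : by);
      const int pm = (bm == dmax) ? SM : ((bx == dmax) ? SX : SY);
      const int Mv = (dmax <= NEG / 2) ? NEG : dmax + s;
      // X from previous row, same column
      const int xm = u[0] + go, xx = u[1] + ge, xy = u[2] + go;
      const int Xv = xm >= xx ? (xm >= xy ? xm : xy) : (xx >= xy ? xx : xy);
      const int px = (Xv == xm) ? SM : ((Xv == xx) ? SX : SY);
      // Y from current row, previous column
      const int ym = ycM + go, yx = ycX + go, yy = ycY + ge;
      const int Yv = ym >= yx ? (ym >= yy ? ym : yy) : (yx >= yy ? yx : yy);
      const int py = (Yv == ym) ? SM : ((Yv == yx) ? SX : SY);
      int* c = cur + 3 * j;
      c[0] = Mv; c[1] = Xv; c[2] = Yv;
      ycM = Mv; ycX = Xv; ycY = Yv;
      trow[j] = (unsigned char)(pm | (px << 2) | (py << 4));
    }
    std::swap(prev, cur);
  }
  AlnCounts out{};
  int sc = prev[3 * m], st = SM;
  if (prev[3 * m + 1] > sc) { sc = prev[3 * m + 1]; st = SX; }
  if (prev[3 * m + 2] > sc) { sc = prev[3 * m + 2]; st = SY; }
  out.score = sc;
  out.a_start = 0; out.a_end = n; out.b_start = 0; out.b_end = m;
  int i = n, j = m;
  std::string ra, rb;
  while (i > 0 || j > 0) {
    const unsigned char t = w.tb[(size_t)i * W + j];
    if (st == SM) {
      tally(out, a[i - 1], b[j - 1]);
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back((*sb)[j - 1]); }
      st = get_pm(t); --i; --j;
    } else if (st == SX) {
      ++out.n_columns;
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back('-'); }
      st = get_px(t); --i;
    } else {
      ++out.n_columns;
      if (want_strings) { ra.push_back('-'); rb.push_back((*sb)[j - 1]); }
      st = get_py(t); --j;
    }
  }
  if (want_strings) {
    out.aln_a.assign(ra.rbegin(), ra.rend());
    out.aln_b.assign(rb.rbegin(), rb.rend());
  }
  return out;
}

static AlnCounts gotoh_local(const std::vector<int>& a, const std::vector<int>& b,
                             int match, int mismatch, int go, int ge,
                             Work& w, bool want_strings,
                             const std::string* sa = nullptr, const std::string* sb = nullptr) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  w.Mp.assign(W, 0); w.Xp.assign(W, NEG); w.Yp.assign(W, NEG);
  w.Mc.resize(W); w.Xc.resize(W); w.Yc.resize(W);
  w.tb.assign((size_t)(n + 1) * W, pack(SSTOP, SM, SM));
  int best_sc = 0, best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    unsigned char* trow = &w.tb[(size_t)i * W];
    const int ai = a[i - 1];
    w.Mc[0] = 0; w.Xc[0] = NEG; w.Yc[0] = NEG;
    trow[0] = pack(SSTOP, SM, SM);
    for (int j = 1; j <= m; ++j) {
      const int s = (ai == b[j - 1] && ai != 4) ? match : mismatch;
      int bm = w.Mp[j - 1], bx = w.Xp[j - 1], by = w.Yp[j - 1];
      int best = bm, pm = SM;
      if (bx > best) { best = bx; pm = SX; }
      if (by > best) { best = by; pm = SY; }
      int Mv = (best <= NEG / 2) ? NEG : best + s;
      if (Mv <= 0) { Mv = 0; pm = SSTOP; }
      int xm = w.Mp[j] + go, xx = w.Xp[j] + ge, xy = w.Yp[j] + go;
      int Xv = xm, px = SM;
      if (xx > Xv) { Xv = xx; px = SX; }
      if (xy > Xv) { Xv = xy; px = SY; }
      int ym = w.Mc[j - 1] + go, yx = w.Xc[j - 1] + go, yy = w.Yc[j - 1] + ge;
      int Yv = ym, py = SM;
      if (yx > Yv) { Yv = yx; py = SX; }
      if (yy > Yv) { Yv = yy; py = SY; }
      w.Mc[j] = Mv; w.Xc[j] = Xv; w.Yc[j] = Yv;
      trow[j] = pack(pm, px, py);
      if (Mv > best_sc) { best_sc = Mv; best_i = i; best_j = j; } // strict: earliest cell wins
    }
    w.Mp.swap(w.Mc); w.Xp.swap(w.Xc); w.Yp.swap(w.Yc);
  }
  AlnCounts out{};
  out.score = best_sc;
  if (best_sc <= 0) {
    out.a_start = out.a_end = out.b_start = out.b_end = 0;
    return out;
  }
  int i = best_i, j = best_j, st = SM;
  std::string ra, rb;
  out.a_end = i; out.b_end = j;
  while (true) {
    const unsigned char t = w.tb[(size_t)i * W + j];
    if (st == SM) {
      if (get_pm(t) == SSTOP) break; // M was clamped to 0 here: local start
      tally(out, a[i - 1], b[j - 1]);
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back((*sb)[j - 1]); }
      st = get_pm(t); --i; --j;
    } else if (st == SX) {
      ++out.n_columns;
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back('-'); }
      st = get_px(t); --i;
    } else {
      ++out.n_columns;
      if (want_strings) { ra.push_back('-'); rb.push_back((*sb)[j - 1]); }
      st = get_py(t); --j;
    }
  }
  out.a_start = i; out.b_start = j;
  if (want_strings) {
    out.aln_a.assign(ra.rbegin(), ra.rend());
    out.aln_b.assign(rb.rbegin(), rb.rend());
  }
  return out;
}

static List counts_to_list(const AlnCounts& c, bool local) {
  List out = List::create(
    _["aligned_a"] = c.aln_a, _["aligned_b"] = c.aln_b,
    _["score"] = c.score, _["n_match"] = c.n_match,
    _["n_mismatch"] = c.n_mismatch, _["n_columns"] = c.n_columns,
    _["n_valid"] = c.n_valid, _["n_transition"] = c.n_ts,
    _["n_transversion"] = c.n_tv);
  if (local) {
    out["a_start"] = c.a_start; out["a_end"] = c.a_end;
    out["b_start"] = c.b_start; out["b_end"] = c.b_end;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend) {
  std::vector<int> ea = encode(a), eb = encode(b);
  Work w;
  AlnCounts c = gotoh_global(ea, eb, match, mismatch, gap_open, gap_extend, w, true, &a, &b);
  return counts_to_list(c, false);
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, int match, int mismatch,
                     int gap_open, int gap_extend) {
  std::vector<int> ea = encode(a), eb = encode(b);
  Work w;
  AlnCounts c = gotoh_local(ea, eb, match, mismatch, gap_open, gap_extend, w, true, &a, &b);
  return counts_to_list(c, true);
}

// Batch global alignment statistics over sequence index pairs (1-based into
// `seqs`). Each pair is aligned in canonical orientation (lexicographically
// smaller encoded sequence first) so the reported counts do not depend on
// the order the pair is given in; all counts are symmetric measures. Returns
// one row per pair: score, n_match, n_mismatch, n_columns, n_valid,
// n_transition, n_transversion.
// [[Rcpp::export]]
IntegerMatrix cpp_pair_stats(CharacterVector seqs, IntegerVector ia, IntegerVector ib,
                             int match, int mismatch, int gap_open, int gap_extend) {
  const int np = ia.size();
  if (ib.size() != np) stop("index vectors differ in length");
  std::vector<std::vector<int> > enc(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) enc[k] = encode(as<std::string>(seqs[k]));
  IntegerMatrix out(np, 7);
  colnames(out) = CharacterVector::create("score", "n_match", "n_mismatch",
                                          "n_columns", "n_valid",
                                          "n_transition", "n_transversion");
  Work w;
  for (int p = 0; p < np; ++p) {
    const std::vector<int>* a = &enc[ia[p] - 1];
    const std::vector<int>* b = &enc[ib[p] - 1];
    if (*b < *a) std::swap(a, b);
    AlnCounts c = gotoh_global(*a, *b, match, mismatch, gap_open, gap_extend, w, false);
    out(p, 0) = c.score; out(p, 1) = c.n_match; out(p, 2) = c.n_mismatch;
    out(p, 3) = c.n_columns; out(p, 4) = c.n_valid; out(p, 5) = c.n_ts; out(p, 6) = c.n_tv;
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
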