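#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Text alphabet codes used throughout the index:
//   0 terminator (unique, smallest, last position only)
//   1 separator  (between sequences; also substituted for N so that no
//                 pattern can match across an N run or a sequence boundary)
//   2 A, 3 C, 4 G, 5 T
static const int ALPHA = 6;

// ---------------------------------------------------------------------------
// SA-IS suffix array construction (induced sorting), worst-case linear.
// s must end with a unique smallest sentinel (code 0).
// ---------------------------------------------------------------------------

static void sais_buckets(const std::vector<int>& s, std::vector<int>& bkt,
                         int K, bool end) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (int c : s) bkt[c]++;
  int sum = 0;
  for (int i = 0; i < K; i++) { sum += bkt[i]; bkt[i] = end ? sum : sum - bkt[i]; }
}

static void sais_induce_L(const std::vector<char>& t, std::vector<int>& sa,
                          const std::vector<int>& s, std::vector<int>& bkt, int K) {
  sais_buckets(s, bkt, K, false);
  int n = (int)s.size();
  for (int i = 0; i < n; i++) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && !t[j]) sa[bkt[s[j]]++] = j;
  }
}

static void sais_induce_S(const std::vector<char>& t, std::vector<int>& sa,
                          const std::vector<int>& s, std::vector<int>& bkt, int K) {
  sais_buckets(s, bkt, K, true);
  int n = (int)s.size();
  for (int i = n - 1; i >= 0; i--) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && t[j]) sa[--bkt[s[j]]] = j;
  }
}

static void sais(const std::vector<int>& s, std::vector<int>& sa, int K) {
  int n = (int)s.size();
  sa.assign(n, -1);
  if (n == 1) { sa[0] = 0; return; }
  std::vector<char> t(n, 0);
  t[n - 1] = 1;  // sentinel is S-type
  for (int i = n - 2; i >= 0; i--)
    t[i] = (s[i] < s[i + 1] || (s[i] == s[i + 1] && t[i + 1])) ? 1 : 0;
  auto isLMS = [&](int i) { return i > 0 && t[i] && !t[i - 1]; };

  std::vector<int> bkt(K);
  sais_buckets(s, bkt, K, true);
  for (int i = 1; i < n; i++) if (isLMS(i)) sa[--bkt[s[i]]] = i;
  sais_induce_L(t, sa, s, bkt, K);
  sais_induce_S(t, sa, s, bkt, K);

  // compact sorted LMS suffixes into the front of sa
  int n1 = 0;
  for (int i = 0; i < n; i++) if (sa[i] > 0 && isLMS(sa[i])) sa[n1++] = sa[i];
  for (int i = n1; i < n; i++) sa[i] = -1;

  // name LMS substrings
  int name = 0, prev = -1;
  for (int i = 0; i < n1; i++) {
    int pos = sa[i];
    bool diff = false;
    if (prev < 0) diff = true;
    else {
      for (int d = 0;; d++) {
        if (pos + d >= n || prev + d >= n) { diff = true; break; }
        if (s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) { diff = true; break; }
        if (d > 0 && (isLMS(pos + d) || isLMS(prev + d))) {
          diff = !(isLMS(pos + d) && isLMS(prev + d));
          break;
        }
      }
    }
    if (diff) { name++; prev = pos; }
    sa[n1 + pos / 2] = name - 1;
  }
  std::vector<int> s1;
  s1.reserve(n1);
  for (int i = n1; i < n; i++) if (sa[i] >= 0) s1.push_back(sa[i]);

  std::vector<int> sa1;
  if (name < n1) {
    sais(s1, sa1, name);
  } else {
    sa1.assign(n1, 0);
    for (int i = 0; i < n1; i++) sa1[s1[i]] = i;
  }

  std::vector<int> lms;
  lms.reserve(n1);
  for (int i = 0; i < n; i++) if (isLMS(i)) lms.push_back(i);

  std::fill(sa.begin(), sa.end(), -1);
  sais_buckets(s, bkt, K, true);
  for (int i = n1 - 1; i >= 0; i--) {
    int j = lms[sa1[i]];
    sa[--bkt[s[j]]] = j;
  }
  sais_induce_L(t, sa, s, bkt, K);
  sais_induce_S(t, sa, s, bkt, K);
}

// [[Rcpp::export]]
IntegerVector suffix_array_cpp(IntegerVector text) {
  int n = text.size();
  std::vector<int> s(text.begin(), text.end());
  if (n == 0 || s[n - 1] != 0) stop("text must end with the terminator code 0");
  std::vector<int> sa;
  sais(s, sa, ALPHA);
  return IntegerVector(sa.begin(), sa.end());
}

// ---------------------------------------------------------------------------
// FM-index: BWT + checkpointed occurrence counts + sampled suffix array.
// ---------------------------------------------------------------------------

static const int CHK = 32;  // occ checkpoint spacing

struct FMIndex {
  int n = 0;
  int sample_rate = 16;
  std::vector<uint8_t> bwt;
  std::array<int, ALPHA> C{};       // # symbols strictly smaller than c
  std::vector<int> occ;             // checkpoints: (n/CHK+1) x ALPHA
  std::vector<int> samp_idx;        // SA row indices carrying samples, ascending
  std::vector<int> samp_val;        // corresponding SA values

  void finish() {
    std::array<int, ALPHA> cnt{};
    int ncp = n / CHK + 1;
    occ.assign((size_t)ncp * ALPHA, 0);
    // i runs to n inclusive so the final checkpoint is written even when
    // n is an exact multiple of CHK (rank(c, n) reads checkpoint n/CHK)
    for (int i = 0; i <= n; i++) {
      if (i % CHK == 0)
        for (int c = 0; c < ALPHA; c++) occ[(size_t)(i / CHK) * ALPHA + c] = cnt[c];
      if (i < n) cnt[bwt[i]]++;
    }
    int below = 0;
    for (int c = 0; c < ALPHA; c++) { C[c] = below; below += cnt[c]; }
  }

  inline int rank(int c, int i) const {  // # of c in bwt[0, i)
    int cp = i / CHK;
    int r = occ[(size_t)cp * ALPHA + c];
    for (int j = cp * CHK; j < i; j++) r += (bwt[j] == c);
    return r;
  }

  inline int LF(int i) const { return C[bwt[i]] + rank(bwt[i], i); }

  // ranks of every symbol at once: one checkpoint scan instead of six
  inline void rank_all(int i, int* out) const {
    int cp = i / CHK;
    const int* base = &occ[(size_t)cp * ALPHA];
    for (int c = 0; c < ALPHA; c++) out[c] = base[c];
    for (int j = cp * CHK; j < i; j++) out[bwt[j]]++;
  }

  // backward-search extension: prepend symbol c
  inline void extend(int lo, int hi, int c, int& nlo, int& nhi) const {
    nlo = C[c] + rank(c, lo);
    nhi = C[c] + rank(c, hi);
  }

  int locate_one(int row) const {
    int steps = 0;
    for (;;) {
      auto it = std::lower_bound(samp_idx.begin(), samp_idx.end(), row);
      if (it != samp_idx.end() && *it == row)
        return samp_val[it - samp_idx.begin()] + steps;
      row = LF(row);
      steps++;
    }
  }
};

// [[Rcpp::export]]
SEXP fm_build_cpp(IntegerVector text, int sample_rate) {
  if (sample_rate < 1) stop("sample_rate must be >= 1");
  int n = text.size();
  std::vector<int> s(text.begin(), text.end());
  if (n == 0 || s[n - 1] != 0) stop("text must end with the terminator code 0");
  std::vector<int> sa;
  sais(s, sa, ALPHA);

  XPtr<FMIndex> p(new FMIndex(), true);
  p->n = n;
  p->sample_rate = sample_rate;
  p->bwt.resize(n);
  for (int i = 0; i < n; i++) p->bwt[i] = (uint8_t)(sa[i] == 0 ? s[n - 1] : s[sa[i] - 1]);
  for (int i = 0; i < n; i++) {
    if (sa[i] % sample_rate == 0) { p->samp_idx.push_back(i); p->samp_val.push_back(sa[i]); }
  }
  p->finish();
  return p;
}

// [[Rcpp::export]]
IntegerVector fm_root_cpp(SEXP xp) {
  XPtr<FMIndex> p(xp);
  return IntegerVector::create(0, p->n);
}

// [[Rcpp::export]]
IntegerVector fm_extend_cpp(SEXP xp, int lo, int hi, int code) {
  XPtr<FMIndex> p(xp);
  if (code < 0 || code >= ALPHA) stop("symbol code out of range");
  int nlo, nhi;
  p->extend(lo, hi, code, nlo, nhi);
  return IntegerVector::create(nlo, nhi);
}

// [[Rcpp::export]]
int fm_count_cpp(SEXP xp, IntegerVector pattern) {
  XPtr<FMIndex> p(xp);
  int lo = 0, hi = p->n;
  for (int i = pattern.size() - 1; i >= 0; i--) {
    int c = pattern[i];
    if (c < 2 || c > 5) return 0;  // anything outside A,C,G,T never matches
    p->extend(lo, hi, c, lo, hi);
    if (lo >= hi) return 0;
  }
  return hi - lo;
}

// [[Rcpp::export]]
IntegerVector fm_locate_cpp(SEXP xp, int lo, int hi) {
  XPtr<FMIndex> p(xp);
  if (lo < 0 || hi > p->n || lo > hi) stop("invalid suffix-array interval");
  std::vector<int> out;
  out.reserve(hi - lo);
  for (int i = lo; i < hi; i++) out.push_back(p->locate_one(i));
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
int fm_length_cpp(SEXP xp) {
  XPtr<FMIndex> p(xp);
  return p->n;
}

// [[Rcpp::export]]
int fm_sample_rate_cpp(SEXP xp) {
  XPtr<FMIndex> p(xp);
  return p->sample_rate;
}

// Serialized payload layout (little-endian int32 unless noted):
//   int32 sample_rate, int32 n, uint8 bwt[n], int32 nsamp,
//   int32 samp_idx[nsamp], int32 samp_val[nsamp]
// Checkpoints and C are rebuilt on load. Deterministic for identical input.

static void push_i32(std::vector<uint8_t>& v, int32_t x) {
  for (int b = 0; b < 4; b++) v.push_back((uint8_t)((x >> (8 * b)) & 0xff));
}
static int32_t read_i32(const uint8_t* p) {
  return (int32_t)((uint32_t)p[0] | ((uint32_t)p[1] << 8) |
                   ((uint32_t)p[2] << 16) | ((uint32_t)p[3] << 24));
}

// [[Rcpp::export]]
RawVector fm_serialize_cpp(SEXP xp) {
  XPtr<FMIndex> p(xp);
  std::vector<uint8_t> v;
  v.reserve(16 + p->bwt.size() + 8 * p->samp_idx.size());
  push_i32(v, p->sample_rate);
  push_i32(v, p->n);
  v.insert(v.end(), p->bwt.begin(), p->bwt.end());
  push_i32(v, (int32_t)p->samp_idx.size());
  for (int x : p->samp_idx) push_i32(v, x);
  for (int x : p->samp_val) push_i32(v, x);
  return RawVector(v.begin(), v.end());
}

// [[Rcpp::export]]
SEXP fm_deserialize_cpp(RawVector raw) {
  size_t len = raw.size();
  const uint8_t* buf = (const uint8_t*)RAW(raw);
  if (len < 12) stop("index payload truncated");
  XPtr<FMIndex> p(new FMIndex(), true);
  p->sample_rate = read_i32(buf);
  p->n = read_i32(buf + 4);
  if (p->sample_rate < 1 || p->n < 1) stop("index payload corrupted");
  size_t off = 8;
  if (len < off + (size_t)p->n + 4) stop("index payload truncated");
  p->bwt.assign(buf + off, buf + off + p->n);
  off += p->n;
  int nsamp = read_i32(buf + off);
  off += 4;
  if (nsamp < 0 || len != off + 8u * (size_t)nsamp) stop("index payload truncated");
  p->samp_idx.resize(nsamp);
  p->samp_val.resize(nsamp);
  for (int i = 0; i < nsamp; i++) { p->samp_idx[i] = read_i32(buf + off); off += 4; }
  for (int i = 0; i < nsamp; i++) { p->samp_val[i] = read_i32(buf + off); off += 4; }
  for (auto b : p->bwt) if (b >= ALPHA) stop("index payload corrupted");
  p->finish();
  return p;
}

// FNV-1a over the text codes; used to tie an index to the genome it was
// built from when databases are cross-checked against an index.
// [[Rcpp::export]]
double text_hash_cpp(IntegerVector text) {
  uint64_t h = 1469598103934665603ull;
  for (int i = 0; i < text.size(); i++) {
    h ^= (uint64_t)(uint8_t)text[i];
    h *= 1099511628211ull;
  }
  return (double)(h & 0x1fffffffffffffull);  // 53 bits, exact in a double
}

// ---------------------------------------------------------------------------
// Off-target search: pruned DFS over backward-search states, simulating a
// reverse-prefix trie traversal. The text pattern is consumed right-to-left:
// for a +-strand site (3' PAM) that means PAM first, then spacer 3'->5'; for
// a --strand site the pattern is the reverse complement, so the spacer is
// consumed 5'->3' (complemented) followed by the complemented PAM.
// ---------------------------------------------------------------------------

struct Step {
  bool is_pam;
  int spacer_pos;   // 1-based from the spacer 5' end; 0 for PAM steps
  uint8_t mask;     // allowed base bitmask (bit b set => base code 2+b allowed)
  int expected;     // expected base 0..3 in text orientation (spacer steps)
};

struct SearchCtx {
  const FMIndex* fm;
  std::vector<Step> steps;
  int L;            // spacer length
  int max_mm, max_rb, max_db;
  bool minus;
  // results
  std::vector<int> r_tpos, r_mm, r_rb, r_db, r_winlen, r_rbpos, r_dbgap;
  std::vector<std::string> r_mism;
  // scratch: mismatch records (spacer_pos, genomic base code 0..3 in spacer orientation)
  std::vector<std::pair<int,int>> mism;
};

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static void emit(SearchCtx& cx, int lo, int hi, int mm, int rb, int db,
                 int rbpos, int dbgap) {
  int winlen = cx.L - rb + db;
  std::vector<std::pair<int,int>> srt(cx.mism);
  std::sort(srt.begin(), srt.end());
  std::string ms;
  for (auto& pr : srt) {
    if (!ms.empty()) ms += ';';
    ms += std::to_string(pr.first);
    ms += ':';
    ms += BASES[pr.second >> 4];   // spacer base
    ms += '>';
    ms += BASES[pr.second & 0xf];  // genomic base (spacer orientation)
  }
  for (int row = lo; row < hi; row++) {
    cx.r_tpos.push_back(cx.fm->locate_one(row));
    cx.r_mm.push_back(mm);
    cx.r_rb.push_back(rb);
    cx.r_db.push_back(db);
    cx.r_winlen.push_back(winlen);
    cx.r_rbpos.push_back(rbpos);
    cx.r_dbgap.push_back(dbgap);
    cx.r_mism.push_back(ms);
  }
}

// si: next step index to consume; spacer_seen: # spacer steps consumed so far
static void dfs(SearchCtx& cx, int si, int lo, int hi, int mm, int rb, int db,
                int rbpos, int dbgap, int spacer_seen) {
  if (lo >= hi) return;
  if (si == (int)cx.steps.size()) {
    emit(cx, lo, hi, mm, rb, db, rbpos, dbgap);
    return;
  }
  const Step& st = cx.steps[si];

  int j = st.spacer_pos;
  int gap = st.is_pam ? 0 : (cx.minus ? j - 1 : j);
  bool db_ok = !st.is_pam && db < cx.max_db && spacer_seen >= 1 &&
               gap >= 1 && gap <= cx.L - 1;

  // child intervals: two checkpoint scans when several bases can branch,
  // individual extensions when only one or two are viable
  int clo[4], chi[4];
  int nmask = st.is_pam ? __builtin_popcount(st.mask) : 0;
  bool all4 = st.is_pam ? (nmask > 2) : (mm < cx.max_mm || db_ok);
  if (all4) {
    int rlo[ALPHA], rhi[ALPHA];
    cx.fm->rank_all(lo, rlo);
    cx.fm->rank_all(hi, rhi);
    for (int b = 0; b < 4; b++) {
      clo[b] = cx.fm->C[2 + b] + rlo[2 + b];
      chi[b] = cx.fm->C[2 + b] + rhi[2 + b];
    }
  } else {
    for (int b = 0; b < 4; b++) { clo[b] = 0; chi[b] = 0; }
    if (st.is_pam) {
      for (int b = 0; b < 4; b++)
        if (st.mask & (1 << b)) cx.fm->extend(lo, hi, 2 + b, clo[b], chi[b]);
    } else {
      cx.fm->extend(lo, hi, 2 + st.expected, clo[st.expected], chi[st.expected]);
    }
  }

  if (st.is_pam) {
    // exact IUPAC match, no mismatch accounting, no bulges
    for (int b = 0; b < 4; b++) {
      if (!(st.mask & (1 << b))) continue;
      if (clo[b] < chi[b])
        dfs(cx, si + 1, clo[b], chi[b], mm, rb, db, rbpos, dbgap, spacer_seen);
    }
    return;
  }

  // substitution / match (expected base first so the exact branch is explored early)
  int order[4] = {st.expected, -1, -1, -1};
  int k = 1;
  for (int b = 0; b < 4; b++) if (b != st.expected) order[k++] = b;
  for (int oi = 0; oi < 4; oi++) {
    int b = order[oi];
    int add = (b == st.expected) ? 0 : 1;
    if (mm + add > cx.max_mm) continue;
    if (clo[b] < chi[b]) {
      if (add) {
        // genomic base in spacer orientation
        int g = cx.minus ? (3 - b) : b;
        int s = cx.minus ? (3 - st.expected) : st.expected;
        cx.mism.push_back({j, (s << 4) | g});
        dfs(cx, si + 1, clo[b], chi[b], mm + 1, rb, db, rbpos, dbgap, spacer_seen + 1);
        cx.mism.pop_back();
      } else {
        dfs(cx, si + 1, clo[b], chi[b], mm, rb, db, rbpos, dbgap, spacer_seen + 1);
      }
    }
  }

  // RNA bulge: skip spacer position j (no genomic symbol consumed).
  // Disallowed at the PAM-adjacent position (L) and at the 5'-terminal
  // position (1), where a terminal gap degenerates to a shorter window.
  if (rb < cx.max_rb && j >= 2 && j <= cx.L - 1) {
    dfs(cx, si + 1, lo, hi, mm, rb + 1, db, j, dbgap, spacer_seen + 1);
  }

  // DNA bulge: extra genomic symbol between two spacer positions (gap is
  // the index between spacer positions gap and gap+1). Requires at least
  // one spacer step already consumed (no gap abutting the PAM) and at
  // least one still to come (no gap beyond the 5' end).
  if (db_ok) {
    for (int b = 0; b < 4; b++) {
      if (clo[b] < chi[b])
        dfs(cx, si, clo[b], chi[b], mm, rb, db + 1, rbpos, gap, spacer_seen);
    }
  }
}

// spacer: base codes 0..3 (A,C,G,T), 5'->3'
// pam_mask: per PAM position, allowed-base bitmask (bit 0=A .. bit 3=T),
//           given 5'->3' in spacer orientation; may be length 0 (PAM-free)
// [[Rcpp::export]]
List fm_search_cpp(SEXP xp, IntegerVector spacer, IntegerVector pam_mask,
                   bool minus_strand, int max_mm, int max_rb, int max_db) {
  XPtr<FMIndex> p(xp);
  SearchCtx cx;
  cx.fm = p.get();
  cx.L = spacer.size();
  cx.max_mm = max_mm;
  cx.max_rb = max_rb;
  cx.max_db = max_db;
  cx.minus = minus_strand;
  int pl = pam_mask.size();

  if (!minus_strand) {
    // text pattern: [window][PAM]; consume right-to-left
    for (int i = pl - 1; i >= 0; i--)
      cx.steps.push_back({true, 0, (uint8_t)pam_mask[i], 0});
    for (int j = cx.L; j >= 1; j--)
      cx.steps.push_back({false, j, 0, spacer[j - 1]});
  } else {
    // text pattern: revcomp([window][PAM]) = [revcomp PAM][revcomp window]
    auto comp_mask = [](int m) {
      int r = 0;
      for (int b = 0; b < 4; b++) if (m & (1 << b)) r |= 1 << (3 - b);
      return r;
    };
    for (int j = 1; j <= cx.L; j++)
      cx.steps.push_back({false, j, 0, 3 - spacer[j - 1]});
    for (int i = 0; i < pl; i++)
      cx.steps.push_back({true, 0, (uint8_t)comp_mask(pam_mask[i]), 0});
  }

  dfs(cx, 0, 0, p->n, 0, 0, 0, 0, 0, 0);

  return List::create(
    _["tpos"] = IntegerVector(cx.r_tpos.begin(), cx.r_tpos.end()),
    _["mm"] = IntegerVector(cx.r_mm.begin(), cx.r_mm.end()),
    _["rna_bulges"] = IntegerVector(cx.r_rb.begin(), cx.r_rb.end()),
    _["dna_bulges"] = IntegerVector(cx.r_db.begin(), cx.r_db.end()),
    _["winlen"] = IntegerVector(cx.r_winlen.begin(), cx.r_winlen.end()),
    _["rb_pos"] = IntegerVector(cx.r_rbpos.begin(), cx.r_rbpos.end()),
    _["db_gap"] = IntegerVector(cx.r_dbgap.begin(), cx.r_dbgap.end()),
    _["mismatch_string"] = CharacterVector(cx.r_mism.begin(), cx.r_mism.end()));
}
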