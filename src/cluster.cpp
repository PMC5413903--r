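#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bit-parallel Levenshtein distance (Myers/Hyyro) for patterns up to 64
// characters, with an Ukkonen-style cutoff: returns the exact distance if
// it is <= k, otherwise some value > k. Peq is the pattern's match mask
// per byte; pl the pattern length; (t, tl) the text.
static int myers_dist(const uint64_t *peq, int pl, const char *t, int tl,
                      int k) {
  int ld = pl - tl;
  if (ld < 0) ld = -ld;
  if (ld > k) return k + 1;
  uint64_t pv = ~UINT64_C(0), mv = 0;
  const uint64_t mask = UINT64_C(1) << (pl - 1);
  int score = pl;
  for (int j = 0; j < tl; ++j) {
    uint64_t eq = peq[(unsigned char) t[j]];
    uint64_t xv = eq | mv;
    uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
    uint64_t ph = mv | ~(xh | pv);
    uint64_t mh = pv & xh;
    score += (ph & mask) != 0;
    score -= (mh & mask) != 0;
    // each remaining text char can lower the score by at most one
    if (score - (tl - 1 - j) > k) return k + 1;
    ph = (ph << 1) | 1;
    pv = (mh << 1) | ~(xv | ph);
    mv = ph & xv;
  }
  return score;
}

struct PatternMask {
  uint64_t peq[256];
  const char *chars;
  int len;
  PatternMask() { std::memset(peq, 0, sizeof(peq)); chars = NULL; len = 0; }
  void set(const char *p, int l) {
    clear();
    chars = p; len = l;
    for (int i = 0; i < l; ++i)
      peq[(unsigned char) p[i]] |= UINT64_C(1) << i;
  }
  void clear() {
    for (int i = 0; i < len; ++i) peq[(unsigned char) chars[i]] = 0;
  }
};

// ACGT composition of a sequence; other characters ignored.
static void base_counts(const char *s, int l, int *cnt) {
  cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0;
  for (int i = 0; i < l; ++i) {
    switch (s[i]) {
      case 'A': case 'a': ++cnt[0]; break;
      case 'C': case 'c': ++cnt[1]; break;
      case 'G': case 'g': ++cnt[2]; break;
      case 'T': case 't': ++cnt[3]; break;
    }
  }
}

// Composition lower bound: one edit changes the base-count L1 distance by
// at most 2, so dist >= L1/2.
static inline int comp_lower_bound(const int *a, const int *b) {
  int l1 = 0;
  for (int i = 0; i < 4; ++i) l1 += std::abs(a[i] - b[i]);
  return (l1 + 1) / 2;
}

// [[Rcpp::export]]
IntegerVector edit_distance_bounded(CharacterVector a, CharacterVector b,
                                    int k) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  PatternMask pm;
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    int la = (int) std::strlen(sa), lb = (int) std::strlen(sb);
    if (la > 64) stop("sequences longer than 64 bases are not supported");
    pm.set(sa, la);
    int d = myers_dist(pm.peq, la, sb, lb, k);
    out[i] = d > k ? NA_INTEGER : d;
  }
  pm.clear();
  return out;
}

// Greedy abundance-ordered centroid clustering. `seqs` must already be
// sorted by decreasing read count (ties broken lexicographically).
// A sequence joins the first (most abundant) centroid whose normalized
// identity, 1 - editdist / max(len), is >= threshold; otherwise it founds
// a new centroid. Returns the 1-based centroid index per input sequence;
// centroid i is the first sequence assigned index i.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold) {
  const R_xlen_t n = seqs.size();
  IntegerVector assign(n);
  if (n == 0) return assign;
  if (threshold <= 0 || threshold > 1)
    stop("identity threshold must be in (0, 1]");
  std::vector<const char *> cs;      // centroid strings
  std::vector<int> clen;             // centroid lengths
  std::vector<int> ccomp;            // 4 base counts per centroid, packed
  cs.reserve(n); clen.reserve(n); ccomp.reserve(4 * n);
  PatternMask pm;
  int qc[4];
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int ls = (int) std::strlen(s);
    if (ls > 64) stop("sequences longer than 64 bases are not supported");
    pm.set(s, ls);
    base_counts(s, ls, qc);
    int hit = 0;
    const size_t nc = cs.size();
    for (size_t c = 0; c < nc; ++c) {
      int lc = clen[c];
      int ml = ls > lc ? ls : lc;
      // identity >= t  <=>  dist <= floor((1-t) * maxlen + eps)
      int k = (int) std::floor((1.0 - threshold) * ml + 1e-9);
      if (comp_lower_bound(qc, &ccomp[4 * c]) > k) continue;
      if (k == 0) {
        if (ls == lc && std::memcmp(s, cs[c], ls) == 0) {
          hit = (int) c + 1; break;
        }
        continue;
      }
      if (myers_dist(pm.peq, ls, cs[c], lc, k) <= k) {
        hit = (int) c + 1; break;
      }
    }
    if (hit) {
      assign[i] = hit;
    } else {
      cs.push_back(s); clen.push_back(ls);
      for (int b = 0; b < 4; ++b) ccomp.push_back(qc[b]);
      assign[i] = (int) cs.size();
    }
    if ((i & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  pm.clear();
  return assign;
}

// Number of mismatches between the first characters of each read and each
// signature (reads shorter than a signature get NA). Rows = reads,
// cols = signatures.
// [[Rcpp::export]]
IntegerMatrix prefix_mismatches(CharacterVector reads,
                                CharacterVector signatures) {
  const R_xlen_t n = reads.size(), m = signatures.size();
  std::vector<const char *> sig(m);
  std::vector<int> slen(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    sig[j] = CHAR(STRING_ELT(signatures, j));
    slen[j] = (int) std::strlen(sig[j]);
  }
  IntegerMatrix out(n, m);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int lr = (int) std::strlen(r);
    for (R_xlen_t j = 0; j < m; ++j) {
      if (lr < slen[j]) { out(i, j) = NA_INTEGER; continue; }
      int mm = 0;
      for (int p = 0; p < slen[j]; ++p) mm += (r[p] != sig[j][p]);
      out(i, j) = mm;
    }
  }
  return out;
}

// First occurrence (1-based) of `pattern` in each sequence, allowing up to
// max_mm substitutions, searching from 1-based position `from`. 0 = not
// found. Exact matches are preferred: a 0-mismatch scan runs first, then
// (if max_mm > 0) a second scan allows mismatches.
// [[Rcpp::export]]
IntegerVector find_flank(CharacterVector seqs, std::string pattern,
                         int max_mm, IntegerVector from) {
  const R_xlen_t n = seqs.size();
  const char *pat = pattern.c_str();
  const int lp = (int) pattern.size();
  if (lp == 0) stop("flank pattern must be non-empty");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int ls = (int) std::strlen(s);
    int f = (from.size() == 1 ? from[0] : from[i]) - 1;
    if (f < 0) f = 0;
    int found = 0;
    int passes = max_mm > 0 ? 2 : 1;
    for (int pass = 0; pass < passes && !found; ++pass) {
      int allow = pass == 0 ? 0 : max_mm;
      for (int p = f; p + lp <= ls; ++p) {
        int mm = 0;
        for (int q = 0; q < lp; ++q) {
          mm += (s[p + q] != pat[q]);
          if (mm > allow) break;
        }
        if (mm <= allow) { found = p + 1; break; }
      }
    }
    out[i] = found;
  }
  return out;
}

// Fraction of bases with Phred quality below min_q (Phred+33 encoding).
// [[Rcpp::export]]
NumericVector low_quality_fraction(CharacterVector quals, int min_q) {
  const R_xlen_t n = quals.size();
  const char cut = (char) (min_q + 33);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int lq = (int) std::strlen(q), low = 0;
    for (int p = 0; p < lq; ++p) low += (q[p] < cut);
    out[i] = lq ? (double) low / lq : 0.0;
  }
  return out;
}
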