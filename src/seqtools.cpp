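#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8)
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 1 | 2 | 4 | 8;
    default: return 0;
  }
}

// Mismatches between an IUPAC pattern and an equal-length window.
// A window base mismatches when its mask shares no bit with the pattern
// code's mask, so N in the window matches every code.
// [[Rcpp::export]]
int C_iupac_mismatches(std::string pattern, std::string window) {
  if (pattern.size() != window.size())
    stop("pattern and window must have equal length");
  int mm = 0;
  for (size_t i = 0; i < pattern.size(); ++i) {
    if ((iupac_mask(pattern[i]) & iupac_mask(window[i])) == 0) ++mm;
  }
  return mm;
}

// Leftmost offset (0-based) within [0, max_shift] at which the IUPAC
// pattern matches seq with <= max_mm mismatches; -1 if none.
// [[Rcpp::export]]
IntegerVector C_iupac_find(CharacterVector seqs, std::string pattern,
                           int max_mm, int max_shift) {
  int n = seqs.size();
  size_t plen = pattern.size();
  std::vector<int> pmask(plen);
  for (size_t j = 0; j < plen; ++j) pmask[j] = iupac_mask(pattern[j]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t slen = strlen(s);
    int hit = -1;
    for (int off = 0; off <= max_shift; ++off) {
      if ((size_t)off + plen > slen) break;
      int mm = 0;
      for (size_t j = 0; j < plen && mm <= max_mm; ++j) {
        if ((pmask[j] & iupac_mask(s[off + j])) == 0) ++mm;
      }
      if (mm <= max_mm) { hit = off; break; }
    }
    out[i] = hit;
  }
  return out;
}

// Best (lowest-mismatch, leftmost on ties) full-scan IUPAC match over a
// whole sequence; returns c(offset, mismatches) or c(-1, NA).
// [[Rcpp::export]]
IntegerVector C_iupac_best_site(std::string seq, std::string pattern,
                                int max_mm) {
  size_t plen = pattern.size(), slen = seq.size();
  std::vector<int> pmask(plen);
  for (size_t j = 0; j < plen; ++j) pmask[j] = iupac_mask(pattern[j]);
  int best_off = -1, best_mm = max_mm + 1;
  if (slen >= plen) {
    for (size_t off = 0; off + plen <= slen; ++off) {
      int mm = 0;
      for (size_t j = 0; j < plen && mm < best_mm; ++j) {
        if ((pmask[j] & iupac_mask(seq[off + j])) == 0) ++mm;
      }
      if (mm < best_mm) { best_mm = mm; best_off = (int)off; }
    }
  }
  IntegerVector out(2);
  if (best_off < 0 || best_mm > max_mm) { out[0] = -1; out[1] = NA_INTEGER; }
  else { out[0] = best_off; out[1] = best_mm; }
  return out;
}

// 2-bit encoding with A<C<G<T so that numeric order == lexicographic order
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Enumerate canonical k-mers (min of k-mer and reverse complement) of one
// sequence; k-mers containing non-ACGT bases are skipped. Appends codes to
// out (one per position, duplicates retained).
static void canonical_codes(const char *s, size_t slen, int k,
                            std::vector<uint64_t> &out) {
  if (slen < (size_t)k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;  // length of current run of ACGT bases
  for (size_t i = 0; i < slen; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int j = k - 1; j >= 0; --j) { s[j] = BITS2BASE[code & 3]; code >>= 2; }
  return s;
}

// Unique canonical k-mers across a set of sequences, as strings.
// [[Rcpp::export]]
CharacterVector C_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> codes;
  for (int i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    codes.clear();
    canonical_codes(s, strlen(s), k, codes);
    for (uint64_t c : codes) seen.insert(c);
  }
  std::vector<uint64_t> sorted(seen.begin(), seen.end());
  std::sort(sorted.begin(), sorted.end());
  CharacterVector out(sorted.size());
  for (size_t i = 0; i < sorted.size(); ++i) out[i] = decode_kmer(sorted[i], k);
  return out;
}

static std::unordered_set<uint64_t> encode_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> out;
  for (int i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)strlen(s) != k) stop("k-mer of wrong length in set");
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) stop("non-ACGT base in k-mer set");
      code = (code << 2) | (uint64_t)b;
    }
    out.insert(code);
  }
  return out;
}

// Per-sequence counts of canonical k-mer positions hitting each exclusive
// set; returns an n x 2 matrix (votes_16S, votes_18S).
// [[Rcpp::export]]
IntegerMatrix C_kmer_votes(CharacterVector seqs, CharacterVector set16,
                           CharacterVector set18, int k) {
  std::unordered_set<uint64_t> s16 = encode_set(set16, k);
  std::unordered_set<uint64_t> s18 = encode_set(set18, k);
  int n = seqs.size();
  IntegerMatrix out(n, 2);
  std::vector<uint64_t> codes;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    codes.clear();
    canonical_codes(s, strlen(s), k, codes);
    int v16 = 0, v18 = 0;
    for (uint64_t c : codes) {
      if (s16.count(c)) ++v16;
      else if (s18.count(c)) ++v18;
    }
    out(i, 0) = v16;
    out(i, 1) = v18;
  }
  return out;
}

// Hamming distance; -1 for unequal lengths.
// [[Rcpp::export]]
int C_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

static int hamming_capped(const char *a, const char *b, size_t len, int cap) {
  int d = 0;
  for (size_t i = 0; i < len; ++i) {
    if (a[i] != b[i] && ++d > cap) return d;
  }
  return d;
}

// Greedy abundance-skew denoiser. Input unique sequences sorted by
// abundance desc (ties lexicographic). A sequence joins the most abundant
// accepted center at Hamming distance d <= max_dist whose abundance
// satisfies abund_u <= abund_c / 2^(alpha*d + 1); otherwise it founds a
// new center. Unequal lengths never merge. Returns 1-based center index
// for every input sequence.
// [[Rcpp::export]]
IntegerVector C_greedy_denoise(CharacterVector seqs, NumericVector abund,
                               double alpha, int max_dist) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<int> centers;
  std::vector<const char *> cseq;
  std::vector<size_t> clen;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t slen = strlen(s);
    int home = -1;
    // centers are stored in processing order, i.e. abundance-descending,
    // so the first admissible center is the most abundant one
    for (size_t j = 0; j < centers.size(); ++j) {
      if (clen[j] != slen) continue;
      int d = hamming_capped(s, cseq[j], slen, max_dist);
      if (d > max_dist) continue;
      double thr = abund[centers[j]] / std::pow(2.0, alpha * d + 1.0);
      if (abund[i] <= thr) { home = centers[j]; break; }
    }
    if (home < 0) {
      centers.push_back(i);
      cseq.push_back(s);
      clen.push_back(slen);
      home = i;
    }
    assign[i] = home + 1;
  }
  return assign;
}

// De novo bimera flags. seqs are unique ASVs with study-wide abundances.
// b is flagged iff some breakpoint p in [1, L-1] exists with b[1..p] equal
// to a prefix of a parent A and b[p+1..L] equal to the positional suffix
// of a parent B, where each parent has abundance >= min_fold * abund(b)
// and the same length as b.
// [[Rcpp::export]]
LogicalVector C_bimera_flags(CharacterVector seqs, NumericVector abund,
                             double min_fold) {
  int n = seqs.size();
  std::vector<const char *> sv(n);
  std::vector<size_t> lv(n);
  for (int i = 0; i < n; ++i) {
    sv[i] = CHAR(STRING_ELT(seqs, i));
    lv[i] = strlen(sv[i]);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    size_t L = lv[i];
    if (L < 2) { out[i] = false; continue; }
    int max_lcp = 0, max_lcs = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i || lv[j] != L) continue;
      if (abund[j] < min_fold * abund[i]) continue;
      size_t p = 0;
      while (p < L && sv[i][p] == sv[j][p]) ++p;
      if ((int)p > max_lcp) max_lcp = (int)p;
      size_t q = 0;
      while (q < L && sv[i][L - 1 - q] == sv[j][L - 1 - q]) ++q;
      if ((int)q > max_lcs) max_lcs = (int)q;
    }
    // breakpoint p must satisfy 1 <= p <= L-1, p <= max_lcp, L-p <= max_lcs
    int lo = std::max(1, (int)L - max_lcs);
    int hi = std::min(max_lcp, (int)L - 1);
    out[i] = (lo <= hi);
  }
  return out;
}

// Overlap-merge read pairs. fwd and rev_rc are the forward read and the
// reverse-complemented reverse read; quals are phred+33 strings aligned to
// the passed sequences. Candidate layouts place the last ov bases of fwd
// against the first ov bases of rev_rc, ov in [min_overlap, min(Lf, Lr)].
// Admissible overlaps need mismatch fraction <= max_mm_frac; the winner
// maximizes matching bases (ties -> longer overlap). Agreement positions
// take the summed quality capped at qcap; disagreements take the
// higher-quality base with quality |q1 - q2| (forward base on exact ties).
// [[Rcpp::export]]
List C_merge_pairs(CharacterVector fwd, CharacterVector fqual,
                   CharacterVector rev_rc, CharacterVector rqual,
                   int min_overlap, double max_mm_frac, int qcap) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *fq = CHAR(STRING_ELT(fqual, i));
    const char *r = CHAR(STRING_ELT(rev_rc, i));
    const char *rq = CHAR(STRING_ELT(rqual, i));
    int Lf = strlen(f), Lr = strlen(r);
    int best_ov = -1, best_match = -1;
    int max_ov = std::min(Lf, Lr);
    for (int ov = min_overlap; ov <= max_ov; ++ov) {
      int mm = 0;
      const char *fo = f + (Lf - ov);
      for (int j = 0; j < ov; ++j) if (fo[j] != r[j]) ++mm;
      if ((double)mm > max_mm_frac * ov) continue;
      int match = ov - mm;
      if (match > best_match || (match == best_match && ov > best_ov)) {
        best_match = match;
        best_ov = ov;
      }
    }
    if (best_ov < 0) { ok[i] = false; mseq[i] = NA_STRING; mqual[i] = NA_STRING; continue; }
    int ov = best_ov;
    std::string seq(f, f + (Lf - ov));
    std::string qual(fq, fq + (Lf - ov));
    for (int j = 0; j < ov; ++j) {
      char fb = f[Lf - ov + j], rb = r[j];
      int q1 = fq[Lf - ov + j] - 33, q2 = rq[j] - 33;
      if (fb == rb) {
        seq.push_back(fb);
        qual.push_back((char)(std::min(q1 + q2, qcap) + 33));
      } else if (q1 >= q2) {
        seq.push_back(fb);
        qual.push_back((char)((q1 - q2) + 33));
      } else {
        seq.push_back(rb);
        qual.push_back((char)((q2 - q1) + 33));
      }
    }
    seq.append(r + ov, r + Lr);
    qual.append(rq + ov, rq + Lr);
    ok[i] = true;
    mseq[i] = seq;
    mqual[i] = qual;
  }
  return List::create(_["merged"] = ok, _["seq"] = mseq, _["qual"] = mqual);
}

// Sum of per-base error probabilities 10^(-Q/10) from phred+33 strings.
// [[Rcpp::export]]
NumericVector C_expected_errors(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    double ee = 0.0;
    for (; *q; ++q) ee += std::pow(10.0, -((double)(*q - 33)) / 10.0);
    out[i] = ee;
  }
  return out;
}
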