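#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// A,C,G,T -> 0..3, anything else -> -1
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encode_seq(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) base_code(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_codes(const std::vector<int8_t> &v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? c : (int8_t)(3 - c);
  }
  return r;
}

static std::string revcomp_string(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// mismatches of read placed at 0-based ref offset `start`, early exit beyond `cap`
static inline int count_mm(const std::vector<int8_t> &ref,
                           const std::vector<int8_t> &read,
                           int start, int cap) {
  int mm = 0;
  const int L = (int) read.size();
  for (int j = 0; j < L; ++j) {
    if (ref[start + j] != read[j]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Placement {
  int mm;     // mismatch count
  int start;  // 0-based
  int strand; // 0 forward, 1 reverse
  bool valid;
  Placement() : mm(0), start(0), strand(0), valid(false) {}
};

// tie order: fewest mismatches, then smallest start, then forward strand
static inline bool better(int mm, int start, int strand, const Placement &best) {
  if (!best.valid) return true;
  if (mm != best.mm) return mm < best.mm;
  if (start != best.start) return start < best.start;
  return strand < best.strand;
}

static void consider(const std::vector<int8_t> &ref,
                     const std::vector<int8_t> &read,
                     int start, int strand, int max_mm, Placement &best) {
  int cap = best.valid ? std::min(max_mm, best.mm) : max_mm;
  int mm = count_mm(ref, read, start, cap);
  if (mm <= max_mm && better(mm, start, strand, best)) {
    best.mm = mm; best.start = start; best.strand = strand; best.valid = true;
  }
}

static Placement align_exhaustive(const std::vector<int8_t> &ref,
                                  const std::vector<int8_t> &fwd,
                                  const std::vector<int8_t> &rev,
                                  int max_mm) {
  Placement best;
  const int n_start = (int) ref.size() - (int) fwd.size() + 1;
  for (int s = 0; s < n_start; ++s) {
    consider(ref, fwd, s, 0, max_mm, best);
    consider(ref, rev, s, 1, max_mm, best);
  }
  return best;
}

typedef std::unordered_map<uint32_t, std::vector<int32_t> > KmerIndex;

static bool hash_kmer(const std::vector<int8_t> &v, int pos, int w, uint32_t &h) {
  h = 0;
  for (int i = 0; i < w; ++i) {
    if (v[pos + i] < 0) return false;
    h = (h << 2) | (uint32_t) v[pos + i];
  }
  return true;
}

static KmerIndex build_index(const std::vector<int8_t> &ref, int w) {
  KmerIndex idx;
  const int n = (int) ref.size() - w + 1;
  for (int i = 0; i < n; ++i) {
    uint32_t h;
    if (hash_kmer(ref, i, w, h)) idx[h].push_back(i);
  }
  return idx;
}

// seed-and-extend: any placement with <= max_mm mismatches leaves one of the
// max_mm + 1 read partitions mismatch-free (pigeonhole), so seeding the prefix
// w-mer of each partition recovers every admissible placement
static Placement align_seeded(const std::vector<int8_t> &ref,
                              const std::vector<int8_t> &fwd,
                              const std::vector<int8_t> &rev,
                              int max_mm, int w, const KmerIndex &idx) {
  Placement best;
  const int L = (int) fwd.size();
  const int n_start = (int) ref.size() - L + 1;
  std::vector<int32_t> cand;
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int8_t> &read = strand == 0 ? fwd : rev;
    cand.clear();
    for (int q = 0; q <= max_mm; ++q) {
      int off = (int)(((long long) q * L) / (max_mm + 1));
      uint32_t h;
      if (!hash_kmer(read, off, w, h)) continue;
      KmerIndex::const_iterator it = idx.find(h);
      if (it == idx.end()) continue;
      for (size_t z = 0; z < it->second.size(); ++z) {
        int s = it->second[z] - off;
        if (s >= 0 && s < n_start) cand.push_back(s);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (size_t z = 0; z < cand.size(); ++z)
      consider(ref, read, cand[z], strand, max_mm, best);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_align_reads(std::string ref, CharacterVector reads, int max_mismatch,
                     bool exhaustive) {
  const std::vector<int8_t> refc = encode_seq(ref);
  const int n = reads.size();
  IntegerVector start(n), mm(n);
  CharacterVector strand(n), seq_fwd(n);

  // index keyed on the partition width of the first read; reads of other
  // lengths fall back to the exhaustive scan
  int w0 = -1;
  KmerIndex idx;
  if (!exhaustive && n > 0) {
    int L0 = LENGTH(STRING_ELT(reads, 0));
    w0 = std::min(15, L0 / (max_mismatch + 1));
    if (w0 >= 6) idx = build_index(refc, w0);
  }

  for (int i = 0; i < n; ++i) {
    std::string rs = as<std::string>(reads[i]);
    if (rs.size() > ref.size())
      stop("read %d is longer than the reference", i + 1);
    std::vector<int8_t> fwd = encode_seq(rs);
    std::vector<int8_t> rev = revcomp_codes(fwd);
    int w = std::min(15, (int) rs.size() / (max_mismatch + 1));
    Placement p = (!exhaustive && w0 >= 6 && w == w0)
      ? align_seeded(refc, fwd, rev, max_mismatch, w0, idx)
      : align_exhaustive(refc, fwd, rev, max_mismatch);
    if (p.valid) {
      start[i] = p.start + 1;
      mm[i] = p.mm;
      strand[i] = p.strand == 0 ? "+" : "-";
      seq_fwd[i] = p.strand == 0 ? rs : revcomp_string(rs);
    } else {
      start[i] = NA_INTEGER;
      mm[i] = NA_INTEGER;
      strand[i] = NA_STRING;
      seq_fwd[i] = NA_STRING;
    }
  }
  return List::create(_["start"] = start, _["mismatches"] = mm,
                      _["strand"] = strand, _["seq_fwd"] = seq_fwd);
}

// per-position counts of observed bases (rows A,C,G,T) from gapless placements
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_length, IntegerVector start, CharacterVector seq) {
  IntegerMatrix counts(4, ref_length);
  for (int i = 0; i < start.size(); ++i) {
    if (start[i] == NA_INTEGER) continue;
    const char *s = CHAR(STRING_ELT(seq, i));
    int L = (int) strlen(s);
    int s0 = start[i] - 1;
    for (int j = 0; j < L; ++j) {
      int k = s0 + j;
      if (k < 0 || k >= ref_length) continue;
      int c = base_code(s[j]);
      if (c >= 0) counts(c, k)++;
    }
  }
  return counts;
}

// does any k-mer of read (either orientation) occur in segment?
// [[Rcpp::export]]
LogicalVector cpp_kmer_prefilter(CharacterVector reads, std::string segment, int k) {
  std::vector<int8_t> seg = encode_seq(segment);
  std::unordered_map<uint32_t, bool> kmers;
  const int n = (int) seg.size() - k + 1;
  for (int i = 0; i < n; ++i) {
    uint32_t h;
    if (hash_kmer(seg, i, k, h)) kmers[h] = true;
  }
  LogicalVector keep(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string rs = as<std::string>(reads[i]);
    bool hit = false;
    for (int o = 0; o < 2 && !hit; ++o) {
      std::vector<int8_t> rc = encode_seq(o == 0 ? rs : revcomp_string(rs));
      const int m = (int) rc.size() - k + 1;
      for (int j = 0; j < m; ++j) {
        uint32_t h;
        if (hash_kmer(rc, j, k, h) && kmers.count(h)) { hit = true; break; }
      }
    }
    keep[i] = hit;
  }
  return keep;
}
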