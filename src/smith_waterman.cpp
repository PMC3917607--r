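#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps. gap_open / gap_extend are
// additive scores (non-positive); gap_extend = 0 prices a gap by its openings
// only, which is what lets long deletions confirm. Gaps are reported after
// leftmost-shift normalization so that identical indels land on identical
// reference intervals across reads (homopolymer slides would otherwise split
// the shared-indel vote).

struct GapRun {
  int kind;              // 1 deletion (segment bases skipped), 2 insertion (read bases extra)
  int ref_a, ref_b;      // deleted segment interval, or anchor==ref_a==ref_b for insertions
  int read_a, read_b;    // inserted read interval (insertions), or read anchor (deletions)
  int size;
};

struct SWAlign {
  double score;
  int seg_start, seg_end, read_start, read_end; // 1-based aligned spans
  int n_mismatch;
  std::vector<GapRun> gaps;
  std::string aseg, aread; // gapped alignment strings
};

static SWAlign sw_core(const std::string &seg, const std::string &read,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = (int) seg.size(), m = (int) read.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
#define AT(M, i, j) M[(size_t)(i) * (m + 1) + (j)]

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(AT(H, i - 1, j) + gap_open, AT(E, i - 1, j) + gap_extend);
      double f = std::max(AT(H, i, j - 1) + gap_open, AT(F, i, j - 1) + gap_extend);
      double s = (seg[i - 1] == read[j - 1]) ? match : mismatch;
      double h = AT(H, i - 1, j - 1) + s;
      h = std::max(std::max(h, e), std::max(f, 0.0));
      AT(E, i, j) = e;
      AT(F, i, j) = f;
      AT(H, i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; } // first max kept: leftmost end
    }
  }

  SWAlign out;
  out.score = best;
  out.n_mismatch = 0;
  if (best <= 0.0) {
    out.seg_start = out.seg_end = out.read_start = out.read_end = 0;
    return out;
  }

  // traceback; preference: diagonal > deletion > insertion, and within a gap
  // prefer extending it (ties only arise through gap placement ambiguity)
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  std::string aseg, aread;
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      double h = AT(H, i, j);
      if (h <= eps || i == 0 || j == 0) break;
      double s = (seg[i - 1] == read[j - 1]) ? match : mismatch;
      if (std::abs(h - (AT(H, i - 1, j - 1) + s)) < eps) {
        aseg.push_back(seg[i - 1]);
        aread.push_back(read[j - 1]);
        if (seg[i - 1] != read[j - 1]) out.n_mismatch++;
        --i; --j;
      } else if (std::abs(h - AT(E, i, j)) < eps) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // segment base gapped against read
      aseg.push_back(seg[i - 1]);
      aread.push_back('-');
      double e = AT(E, i, j);
      bool cont = (i > 1) && std::abs(e - (AT(E, i - 1, j) + gap_extend)) < eps;
      --i;
      state = cont ? 1 : 0;
    } else { // read base gapped against segment
      aseg.push_back('-');
      aread.push_back(read[j - 1]);
      double f = AT(F, i, j);
      bool cont = (j > 1) && std::abs(f - (AT(F, i, j - 1) + gap_extend)) < eps;
      --j;
      state = cont ? 2 : 0;
    }
  }
#undef AT
  std::reverse(aseg.begin(), aseg.end());
  std::reverse(aread.begin(), aread.end());
  out.aseg = aseg;
  out.aread = aread;
  out.seg_start = i + 1;
  out.seg_end = bi;
  out.read_start = j + 1;
  out.read_end = bj;

  // extract gap runs with reference / read coordinates
  int ri = out.seg_start - 1, rj = out.read_start - 1; // 0-based next positions
  for (size_t c = 0; c < aseg.size();) {
    if (aread[c] == '-') {
      int a = ri + 1;
      while (c < aseg.size() && aread[c] == '-') { ++ri; ++c; }
      GapRun g; g.kind = 1; g.ref_a = a; g.ref_b = ri;
      g.read_a = g.read_b = rj; g.size = ri - a + 1;
      out.gaps.push_back(g);
    } else if (aseg[c] == '-') {
      int a = rj + 1;
      while (c < aseg.size() && aseg[c] == '-') { ++rj; ++c; }
      GapRun g; g.kind = 2; g.ref_a = g.ref_b = ri;
      g.read_a = a; g.read_b = rj; g.size = rj - a + 1;
      out.gaps.push_back(g);
    } else {
      ++ri; ++rj; ++c;
    }
  }

  // leftmost-shift normalization of each gap
  for (size_t g = 0; g < out.gaps.size(); ++g) {
    GapRun &gr = out.gaps[g];
    if (gr.kind == 1) {
      while (gr.ref_a > out.seg_start &&
             seg[gr.ref_a - 2] == seg[gr.ref_b - 1]) {
        gr.ref_a--; gr.ref_b--;
      }
    } else {
      while (gr.read_a > out.read_start && gr.ref_a >= out.seg_start &&
             read[gr.read_a - 2] == read[gr.read_b - 1]) {
        gr.read_a--; gr.read_b--; gr.ref_a--;
      }
    }
  }
  return out;
}

static DataFrame gaps_frame(const SWAlign &a) {
  int ng = (int) a.gaps.size();
  CharacterVector kind(ng);
  IntegerVector ra(ng), rb(ng), qa(ng), qb(ng), size(ng);
  for (int g = 0; g < ng; ++g) {
    kind[g] = a.gaps[g].kind == 1 ? "deletion" : "insertion";
    ra[g] = a.gaps[g].ref_a; rb[g] = a.gaps[g].ref_b;
    qa[g] = a.gaps[g].read_a; qb[g] = a.gaps[g].read_b;
    size[g] = a.gaps[g].size;
  }
  return DataFrame::create(_["kind"] = kind, _["ref_start"] = ra,
                           _["ref_end"] = rb, _["read_start"] = qa,
                           _["read_end"] = qb, _["size"] = size,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string segment, double match,
                  double mismatch, double gap_open, double gap_extend) {
  if (read.empty() || segment.empty())
    stop("sw_align: empty sequence");
  SWAlign a = sw_core(segment, read, match, mismatch, gap_open, gap_extend);
  return List::create(
      _["score"] = a.score, _["seg_start"] = a.seg_start,
      _["seg_end"] = a.seg_end, _["read_start"] = a.read_start,
      _["read_end"] = a.read_end, _["n_mismatch"] = a.n_mismatch,
      _["n_gaps"] = (int) a.gaps.size(), _["gaps"] = gaps_frame(a),
      _["aligned_segment"] = a.aseg, _["aligned_read"] = a.aread);
}

static std::string revcomp(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[s.size() - 1 - i]) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// batch SW of pooled reads against one segment; each read is tried as-is and
// reverse-complemented, the better score kept (tie: as-is)
// [[Rcpp::export]]
DataFrame cpp_sw_batch(CharacterVector reads, std::string segment, double match,
                       double mismatch, double gap_open, double gap_extend) {
  const int n = reads.size();
  NumericVector score(n);
  IntegerVector ngaps(n), ref_a(n), ref_b(n), read_a(n), read_b(n), size(n), nmm(n);
  CharacterVector strand(n), kind(n);
  for (int i = 0; i < n; ++i) {
    std::string rs = as<std::string>(reads[i]);
    SWAlign fa = sw_core(segment, rs, match, mismatch, gap_open, gap_extend);
    SWAlign ra = sw_core(segment, revcomp(rs), match, mismatch, gap_open, gap_extend);
    bool use_rev = ra.score > fa.score;
    SWAlign &a = use_rev ? ra : fa;
    score[i] = a.score;
    strand[i] = use_rev ? "-" : "+";
    ngaps[i] = (int) a.gaps.size();
    nmm[i] = a.n_mismatch;
    if (a.gaps.size() == 1) {
      kind[i] = a.gaps[0].kind == 1 ? "deletion" : "insertion";
      ref_a[i] = a.gaps[0].ref_a;
      ref_b[i] = a.gaps[0].ref_b;
      read_a[i] = a.gaps[0].read_a;
      read_b[i] = a.gaps[0].read_b;
      size[i] = a.gaps[0].size;
    } else {
      kind[i] = NA_STRING;
      ref_a[i] = NA_INTEGER;
      ref_b[i] = NA_INTEGER;
      read_a[i] = NA_INTEGER;
      read_b[i] = NA_INTEGER;
      size[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["score"] = score, _["strand"] = strand,
                           _["n_gaps"] = ngaps, _["n_mismatch"] = nmm,
                           _["kind"] = kind, _["ref_start"] = ref_a,
                           _["ref_end"] = ref_b, _["read_start"] = read_a,
                           _["read_end"] = read_b, _["size"] = size,
                           _["stringsAsFactors"] = false);
}

// Confirmation scan over many candidates: an inverted k-mer index over the
// pool picks, per candidate segment, the reads (and orientations) sharing an
// exact k-mer, and only those are SW-aligned. A supporting alignment (one
// gap, <= 1 mismatch) of a read >= 3k-2 bp long always contains an exact
// match run of at least k bases, so the screen cannot drop a supporter.
// Emits one row per aligned read with a single-gap alignment.
// [[Rcpp::export]]
DataFrame cpp_confirm_scan(CharacterVector pool, std::string ref,
                           IntegerVector candidates, int halfwidth, int k,
                           double match, double mismatch, double gap_open,
                           double gap_extend) {
  const int n = pool.size();
  std::vector<std::string> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(pool[i]);
    rev[i] = revcomp(fwd[i]);
  }
  // inverted index: k-mer hash -> (read, orientation)
  std::unordered_map<uint32_t, std::vector<std::pair<int, char> > > idx;
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < 2; ++o) {
      const std::string &s = o == 0 ? fwd[i] : rev[i];
      const int m = (int) s.size() - k + 1;
      uint32_t h = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
      int run = 0;
      for (int j = 0; j < (int) s.size(); ++j) {
        int c;
        switch (s[j]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
        }
        if (c < 0) { run = 0; continue; }
        h = ((h << 2) | (uint32_t) c) & mask;
        if (++run >= k) {
          std::vector<std::pair<int, char> > &v = idx[h];
          if (v.empty() || v.back().first != i || v.back().second != (char) o)
            v.push_back(std::make_pair(i, (char) o));
        }
      }
      (void) m;
    }
  }

  std::vector<int> seen(n, -1);
  std::vector<char> want(n, 0);
  std::vector<int> cand_out, readix, ra, rb, qa, qb, size, nmm;
  std::vector<double> sc;
  std::vector<std::string> kind_out, strand_out;

  for (int ci = 0; ci < candidates.size(); ++ci) {
    int p = candidates[ci];
    int s0 = p - halfwidth - 1; // 0-based segment start
    if (s0 < 0 || s0 + 2 * halfwidth + 1 > (int) ref.size()) continue;
    std::string seg = ref.substr(s0, 2 * halfwidth + 1);
    // mark reads sharing a k-mer with this segment
    std::vector<int> marked;
    uint32_t h = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
    int run = 0;
    for (int j = 0; j < (int) seg.size(); ++j) {
      int c;
      switch (seg[j]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: c = -1;
      }
      if (c < 0) { run = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & mask;
      if (++run >= k) {
        std::unordered_map<uint32_t, std::vector<std::pair<int, char> > >::iterator
          it = idx.find(h);
        if (it == idx.end()) continue;
        for (size_t z = 0; z < it->second.size(); ++z) {
          int i = it->second[z].first;
          char o = it->second[z].second;
          if (seen[i] != ci) { seen[i] = ci; want[i] = 0; marked.push_back(i); }
          want[i] |= (o == 0) ? 1 : 2;
        }
      }
    }
    for (size_t z = 0; z < marked.size(); ++z) {
      int i = marked[z];
      SWAlign best_a;
      best_a.score = -1.0;
      int best_o = 0;
      for (int o = 0; o < 2; ++o) {
        if (!(want[i] & (1 << o))) continue;
        SWAlign a = sw_core(seg, o == 0 ? fwd[i] : rev[i], match, mismatch,
                            gap_open, gap_extend);
        if (a.score > best_a.score) { best_a = a; best_o = o; }
      }
      if (best_a.gaps.size() != 1) continue;
      const GapRun &g = best_a.gaps[0];
      cand_out.push_back(p);
      readix.push_back(i + 1);
      sc.push_back(best_a.score);
      strand_out.push_back(best_o == 0 ? "+" : "-");
      nmm.push_back(best_a.n_mismatch);
      kind_out.push_back(g.kind == 1 ? "deletion" : "insertion");
      ra.push_back(s0 + g.ref_a);  // global 1-based
      rb.push_back(s0 + g.ref_b);
      qa.push_back(g.read_a);
      qb.push_back(g.read_b);
      size.push_back(g.size);
    }
  }
  return DataFrame::create(
      _["candidate"] = cand_out, _["read_index"] = readix, _["score"] = sc,
      _["strand"] = strand_out, _["n_mismatch"] = nmm, _["kind"] = kind_out,
      _["ref_start"] = ra, _["ref_end"] = rb, _["read_start"] = qa,
      _["read_end"] = qb, _["size"] = size, _["stringsAsFactors"] = false);
}
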