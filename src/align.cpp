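// Alignment kernels: seeded gapless mapping (bowtie-like best-stratum
// unique placement) and seeded gapped alignment (Bowtie 2-like, affine
// gaps) against small in-memory genomes.  Coordinates are 0-based.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

static const int NEG = -100000000;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;  // N or anything else: never indexed, never matches
}

// k-mer index over a set of chromosome sequences.
struct SeedIndex {
  int k;
  // packed k-mer -> vector of (chrom << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

static void build_index(const std::vector<std::string>& chroms, int k,
                        SeedIndex& idx) {
  idx.k = k;
  idx.table.clear();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < chroms.size(); ++c) {
    const std::string& s = chroms[c];
    if ((int)s.size() < k) continue;
    uint64_t kmer = 0;
    int valid = 0;  // number of consecutive valid bases accumulated
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        idx.table[kmer].push_back(((uint64_t)c << 32) | pos);
      }
    }
  }
}

static bool pack_kmer(const char* p, int k, uint64_t& out) {
  uint64_t kmer = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(p[i]);
    if (b < 0) return false;
    kmer = (kmer << 2) | (uint64_t)b;
  }
  out = kmer;
  return true;
}

// Count mismatches of read placed at pos on chrom; early exit above cap.
static int count_mismatches(const std::string& chrom, const std::string& read,
                            long pos, int cap) {
  if (pos < 0 || pos + (long)read.size() > (long)chrom.size()) return cap + 1;
  int mm = 0;
  const char* g = chrom.data() + pos;
  const char* r = read.data();
  for (size_t i = 0; i < read.size(); ++i) {
    if (g[i] != r[i] || r[i] == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Gapless best-stratum mapping of a batch of reads.  Returns, per read,
// status 0=unique, 1=ambiguous, 2=no_hit, and the unique placement.
// [[Rcpp::export(name = ".cpp_map_ungapped_batch")]]
DataFrame cpp_map_ungapped_batch(CharacterVector reads,
                                 CharacterVector chrom_seqs,
                                 int max_mismatches) {
  std::vector<std::string> chroms(chrom_seqs.size());
  for (int i = 0; i < chrom_seqs.size(); ++i)
    chroms[i] = as<std::string>(chrom_seqs[i]);

  int n = reads.size();
  std::vector<std::string> rds(n);
  size_t minlen = (size_t)-1;
  for (int i = 0; i < n; ++i) {
    rds[i] = as<std::string>(reads[i]);
    minlen = std::min(minlen, rds[i].size());
  }
  int nseg = max_mismatches + 1;
  int k = 13;
  if (n > 0 && minlen != (size_t)-1)
    k = std::max(4, std::min(13, (int)(minlen / nseg)));

  SeedIndex idx;
  build_index(chroms, k, idx);

  IntegerVector status(n), chrom_out(n), start_out(n), mm_out(n), nbest(n);
  CharacterVector strand_out(n);

  std::vector<uint64_t> cand;
  for (int i = 0; i < n; ++i) {
    const std::string& fwd = rds[i];
    std::string rev = revcomp(fwd);
    int L = fwd.size();
    int best_mm = max_mismatches + 1;
    int best_count = 0;
    long best_pos = -1;
    int best_chrom = -1;
    char best_strand = '+';

    for (int st = 0; st < 2; ++st) {
      const std::string& rd = (st == 0) ? fwd : rev;
      cand.clear();
      for (int s = 0; s < nseg; ++s) {
        int off = (int)((long)s * L / nseg);
        if (off + k > L) off = L - k;
        if (off < 0) continue;
        uint64_t kmer;
        if (!pack_kmer(rd.data() + off, k, kmer)) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
            it = idx.table.find(kmer);
        if (it == idx.table.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          uint64_t v = it->second[j];
          long pos = (long)(v & 0xffffffffULL) - off;
          if (pos < 0) continue;
          cand.push_back((v & 0xffffffff00000000ULL) | (uint64_t)pos);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t j = 0; j < cand.size(); ++j) {
        int c = (int)(cand[j] >> 32);
        long pos = (long)(cand[j] & 0xffffffffULL);
        int mm = count_mismatches(chroms[c], rd, pos, max_mismatches);
        if (mm > max_mismatches) continue;
        if (mm < best_mm) {
          best_mm = mm; best_count = 1;
          best_pos = pos; best_chrom = c; best_strand = (st == 0) ? '+' : '-';
        } else if (mm == best_mm) {
          // distinct placement at the best stratum
          if (!(c == best_chrom && pos == best_pos &&
                best_strand == ((st == 0) ? '+' : '-')))
            ++best_count;
        }
      }
    }

    if (best_mm > max_mismatches) {
      status[i] = 2;
      chrom_out[i] = NA_INTEGER; start_out[i] = NA_INTEGER;
      mm_out[i] = NA_INTEGER; strand_out[i] = NA_STRING; nbest[i] = 0;
    } else if (best_count > 1) {
      status[i] = 1;
      chrom_out[i] = NA_INTEGER; start_out[i] = NA_INTEGER;
      mm_out[i] = NA_INTEGER; strand_out[i] = NA_STRING; nbest[i] = best_count;
    } else {
      status[i] = 0;
      chrom_out[i] = best_chrom + 1;
      start_out[i] = (int)best_pos;
      mm_out[i] = best_mm;
      strand_out[i] = std::string(1, best_strand);
      nbest[i] = 1;
    }
  }

  return DataFrame::create(_["status"] = status, _["chrom"] = chrom_out,
                           _["start"] = start_out, _["strand"] = strand_out,
                           _["mismatches"] = mm_out, _["n_best"] = nbest,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Insertion-aware gapped alignment restricted to a single indel: the best
// full-length placement of the query over {gapless, one insertion, one
// deletion}, on either strand.  Scoring: match +1, mismatch -1, a gap of
// length k costs -(k + 1) (open -2 covering the first gapped base, extend
// -1 per additional base).  Candidate loci come from exact seed matches;
// every placement inside a candidate window is enumerated exhaustively,
// so within seeded windows the result equals a brute-force scan.

struct GapHit {
  int chrom;
  long start;    // 0-based alignment start on the reference
  char strand;
  int score;
  int mismatches;
  char op;       // 'N' gapless, 'I' insertion, 'D' deletion
  int gap_len;   // 0 for gapless
  int a;         // query bases aligned left of the gap
};

struct GapSearch {
  int best;
  std::vector<GapHit> hits;
  size_t cap;
};

static inline void gs_consider(GapSearch& gs, const GapHit& h) {
  if (h.score > gs.best) {
    gs.best = h.score;
    gs.hits.clear();
    gs.hits.push_back(h);
  } else if (h.score == gs.best && gs.hits.size() < gs.cap) {
    gs.hits.push_back(h);
  }
}

static void scan_window(const std::string& q, const std::string& win,
                        long win_off, int chrom, char strand,
                        int max_ins, int max_del, GapSearch& gs) {
  const int L = q.size(), W = win.size();
  if (W < 2 || L < 2) return;
  const int BIG = 1000000;
  // mmL[a][g]: mismatches of q[0..a) placed at window offset g
  std::vector<int> mmL((L + 1) * W, BIG);
  for (int g = 0; g < W; ++g) mmL[g] = 0;
  for (int a = 1; a <= L; ++a) {
    for (int g = 0; g + a <= W; ++g) {
      int prev = mmL[(a - 1) * W + g];
      bool ne = (q[a - 1] != win[g + a - 1]) || q[a - 1] == 'N';
      mmL[a * W + g] = prev + (ne ? 1 : 0);
    }
  }
  // mmR[b][e]: mismatches of the length-b suffix of q ending at window
  // position e (1-based end, 0..W)
  std::vector<int> mmR((L + 1) * (W + 1), BIG);
  for (int e = 0; e <= W; ++e) mmR[e] = 0;
  for (int b = 1; b <= L; ++b) {
    for (int e = b; e <= W; ++e) {
      int prev = mmR[(b - 1) * (W + 1) + e];
      bool ne = (q[L - b] != win[e - b]) || q[L - b] == 'N';
      mmR[b * (W + 1) + e] = prev + (ne ? 1 : 0);
    }
  }
  for (int g = 0; g < W; ++g) {
    if (g + L <= W) {  // gapless
      GapHit h; h.chrom = chrom; h.start = win_off + g; h.strand = strand;
      h.mismatches = mmL[L * W + g];
      h.score = L - 2 * h.mismatches;
      h.op = 'N'; h.gap_len = 0; h.a = L;
      gs_consider(gs, h);
    }
    int kmax = std::min(max_ins, L - 1);
    for (int k = 1; k <= kmax; ++k) {
      int span = L - k;
      int e = g + span;
      if (e > W) break;
      int base = span - (k + 1);
      // a perfect placement at this k scores `base`; larger k only worse
      if (base < gs.best) break;
      for (int a = 0; a <= span; ++a) {
        int ml = mmL[a * W + g];
        int mr = mmR[(span - a) * (W + 1) + e];
        if (ml >= BIG || mr >= BIG) continue;
        GapHit h; h.chrom = chrom; h.start = win_off + g;
        h.strand = strand;
        h.mismatches = ml + mr;
        h.score = base - 2 * h.mismatches;
        h.op = 'I'; h.gap_len = k; h.a = a;
        gs_consider(gs, h);
      }
    }
    for (int d = 1; d <= max_del; ++d) {
      int e = g + L + d;
      if (e > W) break;
      int base = L - (d + 1);
      if (base < gs.best) break;
      for (int a = 1; a <= L - 1; ++a) {  // an M op on each side of the D
        int ml = mmL[a * W + g];
        int mr = mmR[(L - a) * (W + 1) + e];
        if (ml >= BIG || mr >= BIG) continue;
        GapHit h; h.chrom = chrom; h.start = win_off + g;
        h.strand = strand;
        h.mismatches = ml + mr;
        h.score = base - 2 * h.mismatches;
        h.op = 'D'; h.gap_len = d; h.a = a;
        gs_consider(gs, h);
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_map_gapped_batch")]]
List cpp_map_gapped_batch(CharacterVector seqs, CharacterVector chrom_seqs,
                          int seed_k, int window_pad, int max_ins,
                          int max_del) {
  std::vector<std::string> chroms(chrom_seqs.size());
  for (int i = 0; i < chrom_seqs.size(); ++i)
    chroms[i] = as<std::string>(chrom_seqs[i]);
  SeedIndex idx;
  build_index(chroms, seed_k, idx);

  int n = seqs.size();
  List result(n);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(seqs[i]);
    std::string rev = revcomp(fwd);
    int L = fwd.size();
    GapSearch gs; gs.best = NEG; gs.cap = 128;
    for (int st = 0; st < 2; ++st) {
      const std::string& q = (st == 0) ? fwd : rev;
      if (L < seed_k) continue;
      std::vector<std::vector<long> > cands(chroms.size());
      for (int off = 0; off + seed_k <= L; ++off) {
        uint64_t kmer;
        if (!pack_kmer(q.data() + off, seed_k, kmer)) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
            it = idx.table.find(kmer);
        if (it == idx.table.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          uint64_t v = it->second[j];
          int c = (int)(v >> 32);
          long pos = (long)(v & 0xffffffffULL);
          cands[c].push_back(pos - off);
        }
      }
      for (size_t c = 0; c < chroms.size(); ++c) {
        if (cands[c].empty()) continue;
        std::vector<long>& d = cands[c];
        std::sort(d.begin(), d.end());
        d.erase(std::unique(d.begin(), d.end()), d.end());
        size_t a = 0;
        std::vector<std::pair<long, long> > wins;
        while (a < d.size()) {
          size_t b = a;
          while (b + 1 < d.size() && d[b + 1] - d[b] <= window_pad) ++b;
          long lo = d[a] - window_pad;
          long hi = d[b] + L + window_pad;
          if (lo < 0) lo = 0;
          if (hi > (long)chroms[c].size()) hi = chroms[c].size();
          if (hi - lo >= L / 2) wins.push_back(std::make_pair(lo, hi));
          a = b + 1;
        }
        std::vector<std::pair<long, long> > merged;
        for (size_t w = 0; w < wins.size(); ++w) {
          if (!merged.empty() && wins[w].first <= merged.back().second)
            merged.back().second = std::max(merged.back().second,
                                            wins[w].second);
          else merged.push_back(wins[w]);
        }
        for (size_t w = 0; w < merged.size(); ++w) {
          std::string win = chroms[c].substr(
              merged[w].first, merged[w].second - merged[w].first);
          scan_window(q, win, merged[w].first, (int)c,
                      (st == 0) ? '+' : '-', max_ins, max_del, gs);
        }
      }
    }
    if (gs.hits.empty()) { result[i] = R_NilValue; continue; }
    int nk = gs.hits.size();
    IntegerVector chrom(nk), start(nk), score(nk), mm(nk), gap(nk), aa(nk);
    CharacterVector strand(nk), op(nk);
    for (int h = 0; h < nk; ++h) {
      chrom[h] = gs.hits[h].chrom + 1;
      start[h] = (int)gs.hits[h].start;
      strand[h] = std::string(1, gs.hits[h].strand);
      score[h] = gs.hits[h].score;
      mm[h] = gs.hits[h].mismatches;
      op[h] = std::string(1, gs.hits[h].op);
      gap[h] = gs.hits[h].gap_len;
      aa[h] = gs.hits[h].a;
    }
    result[i] = DataFrame::create(
        _["chrom"] = chrom, _["start"] = start, _["strand"] = strand,
        _["score"] = score, _["mismatches"] = mm, _["op"] = op,
        _["gap_len"] = gap, _["a"] = aa,
        _["stringsAsFactors"] = false);
  }
  return result;
}

// Longest exact prefix/suffix extensions used by the exhaustive verifier.
// P[g+1]: longest l with text[g..g+l) == seq[0..l) for g in 0..len(text)-1.
// [[Rcpp::export(name = ".cpp_prefix_match_lengths")]]
IntegerVector cpp_prefix_match_lengths(std::string seq, std::string text) {
  int n = text.size(), L = seq.size();
  IntegerVector out(n);
  for (int g = 0; g < n; ++g) {
    int l = 0;
    int maxl = std::min(L, n - g);
    while (l < maxl && text[g + l] == seq[l] && seq[l] != 'N') ++l;
    out[g] = l;
  }
  return out;
}

// E[p+1]: longest l with text[p-l..p) == seq[L-l..L) for p in 0..len(text).
// [[Rcpp::export(name = ".cpp_suffix_match_lengths")]]
IntegerVector cpp_suffix_match_lengths(std::string seq, std::string text) {
  int n = text.size(), L = seq.size();
  IntegerVector out(n + 1);
  for (int p = 0; p <= n; ++p) {
    int l = 0;
    int maxl = std::min(L, p);
    while (l < maxl && text[p - 1 - l] == seq[L - 1 - l] &&
           seq[L - 1 - l] != 'N') ++l;
    out[p] = l;
  }
  return out;
}
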