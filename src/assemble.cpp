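// Greedy exact-overlap assembly of short reads into contigs.  Repeatedly
// merges the pair with the longest exact suffix/prefix overlap at or above
// min_overlap, in either orientation; containments are absorbed.  Ties are
// broken by the lexicographically smallest member read id.
#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

static inline char cbase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}
static std::string rc(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = cbase(r[i]);
  return r;
}

struct Member {
  int read;     // index into input reads
  int offset;   // 0-based offset of the read within the contig
  bool rev;     // read placed as its reverse complement
};

struct Item {
  std::string seq;
  std::vector<Member> members;
  std::string label;  // lexicographically smallest member id
  bool alive;
};

// longest l in [min_ov, min(lenA,lenB)] with suffix(a, l) == prefix(b, l);
// 0 if none
static int max_overlap(const std::string& a, const std::string& b,
                       int min_ov) {
  int mx = std::min(a.size(), b.size());
  for (int l = mx; l >= min_ov; --l) {
    if (memcmp(a.data() + a.size() - l, b.data(), l) == 0) return l;
  }
  return 0;
}

// first occurrence of b within a, or -1
static int find_sub(const std::string& a, const std::string& b) {
  size_t p = a.find(b);
  return p == std::string::npos ? -1 : (int)p;
}

struct Cand {
  int i, j;     // item indices (ordered: result is i-then-j layout)
  int kind;     // 0: i + j ; 1: i + rc(j) ; 2: rc(i) + j ; 3: j contained
                // in i ; 4: rc(j) contained in i
  int ov;       // overlap length (or length of j for containment)
};

static void eval_pair(const std::vector<Item>& items, int i, int j,
                      int min_ov, std::vector<Cand>& cands) {
  const std::string& A = items[i].seq;
  const std::string& B = items[j].seq;
  std::string Brc = rc(B);
  // containment (treat as maximal overlap)
  // containment outranks any suffix/prefix overlap (ov offset by 1e6)
  int p = find_sub(A, B);
  if (p >= 0 && A.size() >= B.size()) {
    Cand c; c.i = i; c.j = j; c.kind = 3; c.ov = (int)B.size() + 1000000;
    cands.push_back(c);
    return;
  }
  p = find_sub(A, Brc);
  if (p >= 0 && A.size() >= B.size()) {
    Cand c; c.i = i; c.j = j; c.kind = 4; c.ov = (int)B.size() + 1000000;
    cands.push_back(c);
    return;
  }
  int ov;
  if ((ov = max_overlap(A, B, min_ov)) > 0 && ov < (int)B.size() &&
      ov < (int)A.size()) {
    Cand c; c.i = i; c.j = j; c.kind = 0; c.ov = ov; cands.push_back(c);
  }
  if ((ov = max_overlap(A, Brc, min_ov)) > 0 && ov < (int)B.size() &&
      ov < (int)A.size()) {
    Cand c; c.i = i; c.j = j; c.kind = 1; c.ov = ov; cands.push_back(c);
  }
  if ((ov = max_overlap(rc(A), B, min_ov)) > 0 && ov < (int)B.size() &&
      ov < (int)A.size()) {
    Cand c; c.i = i; c.j = j; c.kind = 2; c.ov = ov; cands.push_back(c);
  }
}

static void merge_items(std::vector<Item>& items,
                        const std::vector<std::string>& readseqs,
                        const Cand& c) {
  Item& A = items[c.i];
  Item& B = items[c.j];
  Item merged;
  if (c.kind == 3 || c.kind == 4) {
    bool flip = (c.kind == 4);
    std::string Bseq = flip ? rc(B.seq) : B.seq;
    int p = find_sub(A.seq, Bseq);
    merged.seq = A.seq;
    merged.members = A.members;
    for (size_t k = 0; k < B.members.size(); ++k) {
      Member m = B.members[k];
      int rlen = readseqs[m.read].size();
      if (flip) {
        m.rev = !m.rev;
        m.offset = (int)B.seq.size() - (m.offset + rlen);
      }
      m.offset += p;
      merged.members.push_back(m);
    }
  } else {
    std::string Aseq = A.seq, Bseq = B.seq;
    std::vector<Member> Amem = A.members, Bmem = B.members;
    if (c.kind == 2) {  // rc(A) + B
      Aseq = rc(Aseq);
      for (size_t k = 0; k < Amem.size(); ++k) {
        int rlen = readseqs[Amem[k].read].size();
        Amem[k].rev = !Amem[k].rev;
        Amem[k].offset = (int)A.seq.size() - (Amem[k].offset + rlen);
      }
    }
    if (c.kind == 1) {  // A + rc(B)
      Bseq = rc(Bseq);
      for (size_t k = 0; k < Bmem.size(); ++k) {
        int rlen = readseqs[Bmem[k].read].size();
        Bmem[k].rev = !Bmem[k].rev;
        Bmem[k].offset = (int)B.seq.size() - (Bmem[k].offset + rlen);
      }
    }
    int shift = (int)Aseq.size() - c.ov;
    merged.seq = Aseq + Bseq.substr(c.ov);
    merged.members = Amem;
    for (size_t k = 0; k < Bmem.size(); ++k) {
      Member m = Bmem[k];
      m.offset += shift;
      merged.members.push_back(m);
    }
  }
  merged.alive = true;
  merged.label = A.label < B.label ? A.label : B.label;
  items[c.i] = merged;
  items[c.j].alive = false;
  items[c.j].seq.clear();
  items[c.j].members.clear();
}

// [[Rcpp::export(name = ".cpp_assemble")]]
List cpp_assemble(CharacterVector seqs, CharacterVector ids, int min_overlap) {
  int n = seqs.size();
  std::vector<std::string> readseqs(n);
  std::vector<std::string> readids(n);
  for (int i = 0; i < n; ++i) {
    readseqs[i] = as<std::string>(seqs[i]);
    readids[i] = as<std::string>(ids[i]);
  }
  std::vector<Item> items(n);
  for (int i = 0; i < n; ++i) {
    items[i].seq = readseqs[i];
    Member m; m.read = i; m.offset = 0; m.rev = false;
    items[i].members.push_back(m);
    items[i].label = readids[i];
    items[i].alive = true;
  }

  std::vector<Cand> cands;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) eval_pair(items, i, j, min_overlap, cands);

  while (true) {
    // pick the best candidate: longest overlap, then smallest labels
    int best = -1;
    for (size_t k = 0; k < cands.size(); ++k) {
      const Cand& c = cands[k];
      if (!items[c.i].alive || !items[c.j].alive) continue;
      if (best < 0) { best = k; continue; }
      const Cand& b = cands[best];
      if (c.ov > b.ov) { best = k; continue; }
      if (c.ov < b.ov) continue;
      std::string cl1 = std::min(items[c.i].label, items[c.j].label);
      std::string bl1 = std::min(items[b.i].label, items[b.j].label);
      std::string cl2 = std::max(items[c.i].label, items[c.j].label);
      std::string bl2 = std::max(items[b.i].label, items[b.j].label);
      if (cl1 < bl1 || (cl1 == bl1 && cl2 < bl2) ||
          (cl1 == bl1 && cl2 == bl2 && c.kind < b.kind))
        best = k;
    }
    if (best < 0) break;
    Cand chosen = cands[best];
    merge_items(items, readseqs, chosen);
    // drop stale candidates, re-evaluate merged item against the rest
    std::vector<Cand> keep;
    for (size_t k = 0; k < cands.size(); ++k) {
      const Cand& c = cands[k];
      if (c.i == chosen.i || c.j == chosen.i || c.i == chosen.j ||
          c.j == chosen.j) continue;
      keep.push_back(c);
    }
    cands.swap(keep);
    for (int j = 0; j < n; ++j) {
      if (j == chosen.i || !items[j].alive) continue;
      eval_pair(items, chosen.i, j, min_overlap, cands);
      eval_pair(items, j, chosen.i, min_overlap, cands);
    }
  }

  // emit surviving items
  std::vector<int> order;
  for (int i = 0; i < n; ++i) if (items[i].alive) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return items[a].label < items[b].label; });
  List out(order.size());
  for (size_t o = 0; o < order.size(); ++o) {
    Item& it = items[order[o]];
    int nm = it.members.size();
    IntegerVector ridx(nm), off(nm);
    LogicalVector rev(nm);
    for (int k = 0; k < nm; ++k) {
      ridx[k] = it.members[k].read + 1;
      off[k] = it.members[k].offset;
      rev[k] = it.members[k].rev;
    }
    out[o] = List::create(_["sequence"] = it.seq, _["read"] = ridx,
                          _["offset"] = off, _["rev"] = rev);
  }
  return out;
}
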