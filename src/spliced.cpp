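#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int b2b(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Run { int qs, qe, rs, re; };  // 0-based inclusive k-mer start spans

// Spliced alignment of a transcript-derived query against one genomic
// sequence by exact k-mer anchoring and colinear chaining. Anchors on the
// same diagonal are merged into runs; colinear runs are chained greedily
// from the longest run; runs on the same diagonal separated by small gaps
// (local mismatches/indels) merge into one block, while genomic gaps of at
// least min_intron between consecutive blocks are reported as introns.
// Returns a matrix of blocks with 1-based inclusive [qstart,qend,rstart,rend].
// [[Rcpp::export(name = ".anchor_chain")]]
IntegerMatrix anchor_chain(std::string query, std::string ref, int k,
                           int min_intron) {
  const int nq = (int) query.size(), nr = (int) ref.size();
  IntegerMatrix empty(0, 4);
  if (nq < k || nr < k) return empty;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, int> pos; // kmer -> ref pos, -1 if dup
  {
    uint64_t km = 0; int valid = 0;
    for (int i = 0; i < nr; ++i) {
      int b = b2b(ref[i]);
      if (b < 0) { valid = 0; continue; }
      km = ((km << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        auto it = pos.find(km);
        if (it == pos.end()) pos[km] = i - k + 1; else it->second = -1;
      }
    }
  }

  // anchors grouped by diagonal, merged into runs of consecutive k-mers
  std::vector<std::pair<int, int>> anchors; // (qpos, rpos), unique ref hits
  {
    uint64_t km = 0; int valid = 0;
    for (int i = 0; i < nq; ++i) {
      int b = b2b(query[i]);
      if (b < 0) { valid = 0; continue; }
      km = ((km << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        auto it = pos.find(km);
        if (it != pos.end() && it->second >= 0)
          anchors.push_back({i - k + 1, it->second});
      }
    }
  }
  if (anchors.empty()) return empty;

  // sort by (diag, qpos) then merge consecutive anchors into runs
  std::sort(anchors.begin(), anchors.end(), [](const std::pair<int,int> &a,
                                               const std::pair<int,int> &b) {
    long da = (long) a.second - a.first, db = (long) b.second - b.first;
    if (da != db) return da < db;
    return a.first < b.first;
  });
  std::vector<Run> runs;
  for (size_t i = 0; i < anchors.size(); ++i) {
    long d = (long) anchors[i].second - anchors[i].first;
    if (!runs.empty()) {
      Run &last = runs.back();
      long dl = (long) last.rs - last.qs;
      if (dl == d && anchors[i].first <= last.qe + 1) {
        if (anchors[i].first > last.qe) { last.qe = anchors[i].first; last.re = anchors[i].second; }
        continue;
      }
    }
    runs.push_back({anchors[i].first, anchors[i].first,
                    anchors[i].second, anchors[i].second});
  }
  // run spans cover k-mer starts; extend to base spans
  for (auto &r : runs) { r.qe += k - 1; r.re += k - 1; }

  // greedy chain: seed with the longest run, then add runs compatible in
  // both coordinates (longer runs first; deterministic tie-break on qs)
  std::sort(runs.begin(), runs.end(), [](const Run &a, const Run &b) {
    int la = a.qe - a.qs, lb = b.qe - b.qs;
    if (la != lb) return la > lb;
    return a.qs < b.qs;
  });
  std::vector<Run> chain;
  for (auto &r : runs) {
    bool ok = true;
    for (auto &c : chain) {
      bool before = (r.qe < c.qs + k && r.re < c.rs + k && r.qs < c.qs && r.rs < c.rs);
      bool after  = (r.qs > c.qe - k && r.rs > c.re - k && r.qe > c.qe && r.re > c.re);
      if (!before && !after) { ok = false; break; }
    }
    if (ok) chain.push_back(r);
  }
  std::sort(chain.begin(), chain.end(), [](const Run &a, const Run &b) {
    return a.qs < b.qs;
  });

  // merge chained runs into blocks: same-diagonal-ish small gaps merge,
  // genomic gaps >= min_intron split blocks
  std::vector<Run> blocks;
  for (auto &r : chain) {
    if (!blocks.empty()) {
      Run &b = blocks.back();
      int qgap = r.qs - b.qe - 1;
      int rgap = r.rs - b.re - 1;
      if (rgap - std::max(qgap, 0) < min_intron && qgap < min_intron) {
        if (r.qe > b.qe) b.qe = r.qe;
        if (r.re > b.re) b.re = r.re;
        continue;
      }
    }
    blocks.push_back(r);
  }

  // refine block edges: extend across unanchored bases while they match
  for (size_t i = 0; i < blocks.size(); ++i) {
    Run &b = blocks[i];
    while (b.qs > 0 && b.rs > 0 && query[b.qs - 1] == ref[b.rs - 1] &&
           (i == 0 || b.qs - 1 > blocks[i - 1].qe)) { b.qs--; b.rs--; }
    while (b.qe + 1 < nq && b.re + 1 < nr && query[b.qe + 1] == ref[b.re + 1] &&
           (i + 1 == blocks.size() || b.qe + 1 < blocks[i + 1].qs)) { b.qe++; b.re++; }
  }

  IntegerMatrix out((int) blocks.size(), 4);
  for (size_t i = 0; i < blocks.size(); ++i) {
    out(i, 0) = blocks[i].qs + 1;
    out(i, 1) = blocks[i].qe + 1;
    out(i, 2) = blocks[i].rs + 1;
    out(i, 3) = blocks[i].re + 1;
  }
  return out;
}
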