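#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding; k-mers up to k = 32 fit in one uint64_t.
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_kmer(uint64_t kmer, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (kmer & 3ULL));
    kmer >>= 2;
  }
  return rc;
}

static void count_kmers(const std::string &seq, int k,
                        std::unordered_map<uint64_t, int> &counts) {
  const int n = (int) seq.size();
  if (n < k) return;
  uint64_t kmer = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++valid >= k) counts[kmer]++;
  }
}

// Assemble one UMI bin: de Bruijn graph over the reads and their reverse
// complements, k-mers below min_mult dropped, greedy highest-multiplicity
// walk from the most abundant k-mer (ties broken toward the numerically
// smaller k-mer / lexicographically smaller base for determinism).
// [[Rcpp::export(name = ".dbg_assemble")]]
std::string dbg_assemble(CharacterVector reads, int k, int min_mult) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    count_kmers(s, k, counts);
    std::string rc(s.rbegin(), s.rend());
    for (auto &c : rc) {
      int b = base2bits(c);
      c = (b < 0) ? 'N' : BITS2BASE[3 - b];
    }
    count_kmers(rc, k, counts);
  }
  // multiplicity filter
  for (auto it = counts.begin(); it != counts.end();) {
    if (it->second < min_mult) it = counts.erase(it); else ++it;
  }
  if (counts.empty()) return "";

  uint64_t seed = 0; int best = -1;
  for (auto &kv : counts) {
    if (kv.second > best || (kv.second == best && kv.first < seed)) {
      best = kv.second; seed = kv.first;
    }
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> visited;
  visited.insert(seed);

  // decode seed
  std::string contig(k, 'N');
  {
    uint64_t t = seed;
    for (int i = k - 1; i >= 0; --i) { contig[i] = BITS2BASE[t & 3ULL]; t >>= 2; }
  }

  // extend right
  uint64_t cur = seed;
  for (;;) {
    int bestCnt = 0; int bestB = -1;
    for (int b = 0; b < 4; ++b) {
      uint64_t nxt = ((cur << 2) | (uint64_t) b) & mask;
      auto it = counts.find(nxt);
      if (it == counts.end() || visited.count(nxt)) continue;
      if (it->second > bestCnt) { bestCnt = it->second; bestB = b; }
      // ties fall to the smaller base because b ascends
    }
    if (bestB < 0) break;
    cur = ((cur << 2) | (uint64_t) bestB) & mask;
    visited.insert(cur);
    contig.push_back(BITS2BASE[bestB]);
  }
  // extend left
  cur = seed;
  std::string left;
  for (;;) {
    int bestCnt = 0; int bestB = -1;
    for (int b = 0; b < 4; ++b) {
      uint64_t prv = (((uint64_t) b) << (2 * (k - 1))) | (cur >> 2);
      auto it = counts.find(prv);
      if (it == counts.end() || visited.count(prv)) continue;
      if (it->second > bestCnt) { bestCnt = it->second; bestB = b; }
    }
    if (bestB < 0) break;
    cur = (((uint64_t) bestB) << (2 * (k - 1))) | (cur >> 2);
    visited.insert(cur);
    left.push_back(BITS2BASE[bestB]);
  }
  std::string out(left.rbegin(), left.rend());
  out += contig;
  return out;
}

// Overlay member reads on a contig by majority k-mer anchor offset (both
// orientations tried) and accumulate the per-column pileup used for the
// consensus sequence, depth/agreement profiles and quality model.
// quals: Phred scores per read (list of integer vectors not needed; we take
// the FASTQ strings and an offset of 33).
// [[Rcpp::export(name = ".consensus_profile")]]
List consensus_profile(std::string contig, CharacterVector reads,
                       CharacterVector quals, int k) {
  const int L = (int) contig.size();
  // index contig k-mers -> first position; duplicates flagged
  std::unordered_map<uint64_t, int> pos_of;
  std::unordered_set<uint64_t> dup;
  {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t kmer = 0; int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b = base2bits(contig[i]);
      if (b < 0) { valid = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        int start = i - k + 1;
        auto it = pos_of.find(kmer);
        if (it == pos_of.end()) pos_of[kmer] = start; else dup.insert(kmer);
      }
    }
  }

  std::vector<std::array<int, 4>> baseCounts(L, {0, 0, 0, 0});
  std::vector<double> errSum(L, 0.0);
  std::vector<int> depth(L, 0);
  int used = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    std::string q = as<std::string>(quals[r]);
    const int n = (int) s.size();
    if (n < k) continue;
    std::string rc(s.rbegin(), s.rend());
    for (auto &c : rc) { int b = base2bits(c); c = (b < 0) ? 'N' : BITS2BASE[3 - b]; }

    int bestVotes = 0, bestOff = 0, bestOri = 0;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &ss = ori ? rc : s;
      std::unordered_map<int, int> votes;
      uint64_t kmer = 0; int valid = 0;
      for (int i = 0; i < n; ++i) {
        int b = base2bits(ss[i]);
        if (b < 0) { valid = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t) b) & mask;
        if (++valid >= k && !dup.count(kmer)) {
          auto it = pos_of.find(kmer);
          if (it != pos_of.end()) votes[it->second - (i - k + 1)]++;
        }
      }
      for (auto &kv : votes) {
        if (kv.second > bestVotes) { bestVotes = kv.second; bestOff = kv.first; bestOri = ori; }
      }
    }
    if (bestVotes < 1) continue;
    used++;
    const std::string &ss = bestOri ? rc : s;
    // quality string follows the read; reverse it for the RC orientation
    for (int i = 0; i < n; ++i) {
      int cp = bestOff + i;
      if (cp < 0 || cp >= L) continue;
      int b = base2bits(ss[i]);
      if (b < 0) continue;
      baseCounts[cp][b]++;
      depth[cp]++;
      int qi = bestOri ? (n - 1 - i) : i;
      int Q = (int) q[qi] - 33;
      if (Q < 0) Q = 0;
      errSum[cp] += std::pow(10.0, -Q / 10.0);
    }
  }

  std::string cons(L, 'N');
  IntegerVector dep(L), agree(L);
  NumericVector meanErr(L);
  for (int i = 0; i < L; ++i) {
    int bestB = 0, bestC = -1;
    for (int b = 0; b < 4; ++b) {
      if (baseCounts[i][b] > bestC) { bestC = baseCounts[i][b]; bestB = b; }
      // ties resolve to the lexicographically smaller base since b ascends
    }
    cons[i] = (depth[i] > 0) ? BITS2BASE[bestB] : contig[i];
    dep[i] = depth[i];
    agree[i] = (depth[i] > 0) ? bestC : 0;
    meanErr[i] = (depth[i] > 0) ? errSum[i] / depth[i] : 1.0;
  }
  return List::create(_["sequence"] = cons, _["depth"] = dep,
                      _["agree"] = agree, _["mean_read_err"] = meanErr,
                      _["reads_used"] = used);
}
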