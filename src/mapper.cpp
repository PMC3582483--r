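// Seed-and-extend ungapped read mapper and pileup accumulator.
//
// The mapper is deliberately ungapped and end-to-end: at the 99%-identity
// acceptance threshold used for PSV detection a 100-bp read admits at most
// one mismatch, so indel tolerance is pointless and exact mismatch
// accounting is what matters. Seeds are exact k-mers taken at regular
// offsets across the read (pigeonhole: a read with m mismatches still has
// a clean seed as long as m < number of seeds).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

struct SeedHit { int tid; int pos; };

class KmerIndex {
public:
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<SeedHit> > map;

  KmerIndex(const CharacterVector& transcripts, int k_) : k(k_) {
    int n = transcripts.size();
    seqs.reserve(n);
    for (int i = 0; i < n; ++i) seqs.push_back(as<std::string>(transcripts[i]));
    for (int t = 0; t < n; ++t) {
      const std::string& s = seqs[t];
      int L = (int)s.size();
      if (L < k) continue;
      uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int run = 0;  // valid-base run length
      for (int i = 0; i < L; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          map[key].push_back(SeedHit{t, i - k + 1});
        }
      }
    }
  }

  bool kmer_key(const std::string& s, int from, uint64_t* key) const {
    uint64_t v = 0;
    for (int i = from; i < from + k; ++i) {
      int c = base_code(s[i]);
      if (c < 0) return false;
      v = (v << 2) | (uint64_t)c;
    }
    *key = v;
    return true;
  }
};

static int count_mismatches(const std::string& t, int offset,
                            const std::string& r, int best) {
  int mm = 0;
  int L = (int)r.size();
  for (int i = 0; i < L; ++i) {
    if (t[offset + i] != r[i]) {
      if (++mm > best) return mm;  // early exit past current best
    }
  }
  return mm;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector transcripts,
                   int k, double min_identity) {
  if (transcripts.size() == 0) stop("empty transcript set");
  KmerIndex idx(transcripts, k);

  std::vector<int> out_read, out_tid, out_start, out_mm, out_len;
  std::vector<int> out_strand;  // 1 = plus, -1 = minus

  struct Cand { int tid; int offset; int strand; };

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp_base(fwd[i]);

    int best = L;  // mismatch count of current best placement
    std::vector<Cand> best_cands;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& r = (strand == 0) ? fwd : rev;
      // seed offsets: non-overlapping k-mers plus one flush to the 3' end
      std::vector<int> seed_from;
      for (int p = 0; p + k <= L; p += k) seed_from.push_back(p);
      if (seed_from.empty() || seed_from.back() != L - k)
        seed_from.push_back(L - k);

      std::vector<std::pair<int,int> > seen;  // (tid, offset) this strand
      for (size_t si = 0; si < seed_from.size(); ++si) {
        uint64_t key;
        if (!idx.kmer_key(r, seed_from[si], &key)) continue;
        std::unordered_map<uint64_t, std::vector<SeedHit> >::const_iterator
          it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        const std::vector<SeedHit>& hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int offset = hits[h].pos - seed_from[si];
          int tid = hits[h].tid;
          if (offset < 0) continue;
          const std::string& t = idx.seqs[tid];
          if (offset + L > (int)t.size()) continue;  // end-to-end only
          bool dup = false;
          for (size_t z = 0; z < seen.size(); ++z)
            if (seen[z].first == tid && seen[z].second == offset) {
              dup = true; break;
            }
          if (dup) continue;
          seen.push_back(std::make_pair(tid, offset));
          int mm = count_mismatches(t, offset, r, best);
          if (mm < best) {
            best = mm;
            best_cands.clear();
          }
          if (mm == best) {
            Cand c; c.tid = tid; c.offset = offset;
            c.strand = (strand == 0) ? 1 : -1;
            best_cands.push_back(c);
          }
        }
      }
    }

    if (best_cands.empty()) continue;
    double identity = (double)(L - best) / (double)L;
    if (identity < min_identity) continue;
    // a read tied between transcripts is reported on all of them, but only
    // once per transcript (drop duplicate-offset ties within a transcript)
    std::vector<int> tid_done;
    for (size_t c = 0; c < best_cands.size(); ++c) {
      bool dup = false;
      for (size_t z = 0; z < tid_done.size(); ++z)
        if (tid_done[z] == best_cands[c].tid) { dup = true; break; }
      if (dup) continue;
      tid_done.push_back(best_cands[c].tid);
      out_read.push_back(ri + 1);
      out_tid.push_back(best_cands[c].tid + 1);
      out_start.push_back(best_cands[c].offset + 1);
      out_strand.push_back(best_cands[c].strand);
      out_mm.push_back(best);
      out_len.push_back(L);
    }
  }

  return List::create(_["read"] = wrap(out_read),
                      _["transcript"] = wrap(out_tid),
                      _["start"] = wrap(out_start),
                      _["strand"] = wrap(out_strand),
                      _["n_mismatches"] = wrap(out_mm),
                      _["aligned_len"] = wrap(out_len));
}

// [[Rcpp::export(name = ".build_pileup_cpp")]]
List build_pileup_cpp(IntegerVector read_idx, IntegerVector t_idx,
                      IntegerVector start, IntegerVector strand,
                      CharacterVector reads, CharacterVector transcripts) {
  int nt = transcripts.size();
  std::vector<int> tlen(nt);
  std::vector<std::vector<int> > counts(nt);
  for (int t = 0; t < nt; ++t) {
    tlen[t] = LENGTH(STRING_ELT(transcripts, t));
    counts[t].assign((size_t)tlen[t] * 4, 0);
  }
  for (int i = 0; i < read_idx.size(); ++i) {
    std::string r = as<std::string>(reads[read_idx[i] - 1]);
    int t = t_idx[i] - 1;
    int off = start[i] - 1;
    int L = (int)r.size();
    if (off < 0 || off + L > tlen[t])
      stop("placement overhangs transcript end (mapper contract violation)");
    if (strand[i] < 0) {  // contribute the transcript-forward base
      std::string rc(L, 'N');
      for (int j = 0; j < L; ++j) rc[L - 1 - j] = comp_base(r[j]);
      r = rc;
    }
    for (int j = 0; j < L; ++j) {
      int c = base_code(r[j]);
      if (c >= 0) counts[t][(size_t)(off + j) * 4 + c]++;
    }
  }
  // emit covered positions only
  std::vector<int> o_t, o_pos, oA, oC, oG, oT;
  for (int t = 0; t < nt; ++t) {
    for (int p = 0; p < tlen[t]; ++p) {
      int a = counts[t][(size_t)p * 4 + 0], c = counts[t][(size_t)p * 4 + 1];
      int g = counts[t][(size_t)p * 4 + 2], u = counts[t][(size_t)p * 4 + 3];
      if (a + c + g + u == 0) continue;
      o_t.push_back(t + 1); o_pos.push_back(p + 1);
      oA.push_back(a); oC.push_back(c); oG.push_back(g); oT.push_back(u);
    }
  }
  return List::create(_["transcript"] = wrap(o_t), _["pos"] = wrap(o_pos),
                      _["A"] = wrap(oA), _["C"] = wrap(oC),
                      _["G"] = wrap(oG), _["T"] = wrap(oT));
}
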