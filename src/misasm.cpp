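#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit base encoding; anything but ACGT (upper case) is invalid
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// sorted (kmer, packed position) index over a set of sequences.
// packed = (seq_index << 40) | pos ; limits sequences to 2^40 bp.
struct KmerIndex {
  std::vector<std::pair<uint64_t, uint64_t> > entries;
  int k;
};

static void index_sequences(const std::vector<std::string>& seqs, int k,
                            KmerIndex& idx) {
  idx.k = k;
  idx.entries.clear();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t si = 0; si < seqs.size(); ++si) {
    const std::string& s = seqs[si];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        idx.entries.push_back(std::make_pair(key, ((uint64_t)si << 40) | pos));
      }
    }
  }
  std::sort(idx.entries.begin(), idx.entries.end());
}

// hits for one kmer key; returns [first, last) range in idx.entries
static inline std::pair<size_t, size_t> lookup(const KmerIndex& idx,
                                               uint64_t key) {
  std::pair<uint64_t, uint64_t> lo(key, 0);
  std::pair<uint64_t, uint64_t> hi(key + 1, 0);
  size_t a = std::lower_bound(idx.entries.begin(), idx.entries.end(), lo) -
             idx.entries.begin();
  size_t b = (key == ~0ULL)
                 ? idx.entries.size()
                 : std::lower_bound(idx.entries.begin(), idx.entries.end(),
                                    hi) - idx.entries.begin();
  return std::make_pair(a, b);
}

// Collinear exact-anchor runs between one query and one reference sequence.
// Anchors of length k sharing a diagonal and spaced by <= gap_max query bases
// are merged into one run; runs shorter than min_len are dropped.
// Kmers occurring more than max_hits times in the reference are skipped as
// overly repetitive. Coordinates are 0-based half-open.
// [[Rcpp::export]]
DataFrame cpp_anchor_runs(std::string query, std::string ref, int k,
                          int gap_max, int min_len, int max_hits) {
  std::vector<std::string> refs(1, ref);
  KmerIndex idx;
  index_sequences(refs, k, idx);

  struct Run { int64_t qstart, qlast; };
  std::map<int64_t, Run> open;  // diagonal -> run
  std::vector<int64_t> out_qs, out_qe, out_rs, out_re;

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0;
  for (size_t i = 0; i < query.size(); ++i) {
    int b = base2bit(query[i]);
    if (b < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int64_t qpos = (int64_t)(i + 1 - k);
    std::pair<size_t, size_t> rng = lookup(idx, key);
    if (rng.second - rng.first == 0 ||
        (int)(rng.second - rng.first) > max_hits)
      continue;
    for (size_t e = rng.first; e < rng.second; ++e) {
      int64_t rpos = (int64_t)(idx.entries[e].second & ((1ULL << 40) - 1));
      int64_t diag = rpos - qpos;
      std::map<int64_t, Run>::iterator it = open.find(diag);
      if (it == open.end()) {
        Run r; r.qstart = qpos; r.qlast = qpos;
        open[diag] = r;
      } else if (qpos - it->second.qlast <= gap_max) {
        it->second.qlast = qpos;
      } else {
        // close and emit
        int64_t qs = it->second.qstart, qe = it->second.qlast + k;
        if (qe - qs >= min_len) {
          out_qs.push_back(qs); out_qe.push_back(qe);
          out_rs.push_back(qs + diag); out_re.push_back(qe + diag);
        }
        it->second.qstart = qpos; it->second.qlast = qpos;
      }
    }
  }
  for (std::map<int64_t, Run>::iterator it = open.begin(); it != open.end();
       ++it) {
    int64_t qs = it->second.qstart, qe = it->second.qlast + k;
    if (qe - qs >= min_len) {
      out_qs.push_back(qs); out_qe.push_back(qe);
      out_rs.push_back(qs + it->first); out_re.push_back(qe + it->first);
    }
  }
  int n = out_qs.size();
  IntegerVector qs(n), qe(n), rs(n), re(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = out_qs[i]; qe[i] = out_qe[i];
    rs[i] = out_rs[i]; re[i] = out_re[i];
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["r_start"] = rs, _["r_end"] = re);
}

// Seed-and-extend placement of short reads on a set of scaffolds.
// For each read, seeds of length k at the given offsets (on both strands)
// propose candidate placements; each candidate is scored by full-length
// Hamming comparison and placements with <= max_mismatch kept. Among the
// equal-best placements one is chosen uniformly at random (R RNG) and the
// number of equal-best placements reported. Reads with no valid placement
// are omitted.
// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector scaffolds, int k,
                     IntegerVector offsets, int max_mismatch) {
  int ns = scaffolds.size();
  std::vector<std::string> scafs(ns);
  for (int i = 0; i < ns; ++i) scafs[i] = as<std::string>(scaffolds[i]);
  KmerIndex idx;
  index_sequences(scafs, k, idx);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<int> o_read, o_scaf, o_pos, o_strand, o_nbest, o_mism;
  RNGScope rng;

  struct Cand { int scaf; int64_t pos; int strand; };
  std::vector<Cand> cands;
  std::vector<Cand> best;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = fwd.size();
    if (len < k) continue;
    std::string rev(len, 'N');
    for (int i = 0; i < len; ++i) rev[i] = complement(fwd[len - 1 - i]);

    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;
      for (int oi = 0; oi < offsets.size(); ++oi) {
        int off = offsets[oi];
        if (off < 0 || off + k > len) continue;
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bit(rd[off + j]);
          if (b < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        std::pair<size_t, size_t> rng2 = lookup(idx, key);
        if (rng2.second - rng2.first > 64) continue;  // hyper-repetitive seed
        for (size_t e = rng2.first; e < rng2.second; ++e) {
          int si = (int)(idx.entries[e].second >> 40);
          int64_t pos =
              (int64_t)(idx.entries[e].second & ((1ULL << 40) - 1)) - off;
          bool dup = false;
          for (size_t c = 0; c < cands.size(); ++c)
            if (cands[c].scaf == si && cands[c].pos == pos &&
                cands[c].strand == strand) { dup = true; break; }
          if (!dup) {
            Cand cd; cd.scaf = si; cd.pos = pos; cd.strand = strand;
            cands.push_back(cd);
          }
        }
      }
    }
    int best_mm = max_mismatch + 1;
    best.clear();
    for (size_t c = 0; c < cands.size(); ++c) {
      int si = cands[c].scaf;
      int64_t pos = cands[c].pos;
      if (pos < 0 || pos + len > (int64_t)scafs[si].size()) continue;
      const std::string& rd = (cands[c].strand == 0) ? fwd : rev;
      int mm = 0;
      const char* sc = scafs[si].c_str() + pos;
      for (int j = 0; j < len; ++j) {
        if (rd[j] != sc[j] && ++mm > max_mismatch) break;
      }
      if (mm > max_mismatch) continue;
      if (mm < best_mm) { best_mm = mm; best.clear(); }
      if (mm == best_mm) best.push_back(cands[c]);
    }
    if (best.empty()) continue;
    int pick = 0;
    if (best.size() > 1)
      pick = (int)(unif_rand() * best.size()) % best.size();
    o_read.push_back(ri + 1);
    o_scaf.push_back(best[pick].scaf + 1);
    o_pos.push_back((int)best[pick].pos);
    o_strand.push_back(best[pick].strand == 0 ? 1 : -1);
    o_nbest.push_back((int)best.size());
    o_mism.push_back(best_mm);
  }
  return List::create(_["read"] = wrap(o_read), _["scaffold"] = wrap(o_scaf),
                      _["pos"] = wrap(o_pos), _["strand"] = wrap(o_strand),
                      _["n_best"] = wrap(o_nbest), _["mism"] = wrap(o_mism));
}

// Base-count pileup over one scaffold. seqs[i] holds the aligned bases of
// read i in scaffold coordinates starting at pos0[i] (0-based); '-' and 'N'
// contribute nothing. Returns a 4 x L count matrix (A,C,G,T rows), the
// per-base count of covering multi-placed reads (counted where the read
// contributes a base), and the number of rejected out-of-bounds reads.
// [[Rcpp::export]]
List cpp_pileup(int L, IntegerVector pos0, CharacterVector seqs,
                LogicalVector multi) {
  IntegerMatrix counts(4, L);
  IntegerVector mcnt(L);
  int rejected = 0;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int p = pos0[i];
    if (p < 0 || p + (int)s.size() > L) { ++rejected; continue; }
    bool is_m = multi[i];
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2bit(s[j]);
      if (b < 0) continue;
      ++counts(b, p + j);
      if (is_m) ++mcnt[p + j];
    }
  }
  return List::create(_["counts"] = counts, _["multi"] = mcnt,
                      _["rejected"] = rejected);
}

// Apply point substitutions to reads (1-based positions within each read).
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector reads, IntegerVector idx,
                                  IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(reads);
  for (int i = 0; i < idx.size(); ++i) {
    std::string s = as<std::string>(out[idx[i] - 1]);
    int p = pos[i] - 1;
    if (p >= 0 && p < (int)s.size()) {
      s[p] = as<std::string>(base[i])[0];
      out[idx[i] - 1] = s;
    }
  }
  return out;
}
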