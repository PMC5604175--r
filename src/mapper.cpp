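#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; returns false if any non-ACGT base in window.
static inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c;
    switch (s[i]) {
      case 'A': c = 0; break;
      case 'C': c = 1; break;
      case 'G': c = 2; break;
      case 'T': c = 3; break;
      default: return false;
    }
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Hamming distance with early exit above limit; -1 if exceeds limit.
static inline int hamming_capped(const char* a, const char* b, int n, int limit) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      if (++mm > limit) return -1;
    }
  }
  return mm;
}

struct SeedIndex {
  int k;
  // kmer -> packed (contig << 40 | pos) entries
  std::unordered_map<uint64_t, std::vector<uint64_t> > map;
};

static void build_index(const std::vector<std::string>& contigs, int k, SeedIndex& idx) {
  idx.k = k;
  for (size_t ci = 0; ci < contigs.size(); ++ci) {
    const std::string& s = contigs[ci];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t v;
      if (encode_kmer(s.c_str() + p, k, v))
        idx.map[v].push_back(((uint64_t)ci << 40) | (uint64_t)p);
    }
  }
}

// Seed-and-extend read mapper against a set of contigs.
//
// Exact seeds are taken at both ends (and the middle) of the read on each
// strand; every candidate placement implied by a seed hit is scored by full
// Hamming distance (no indels). All placements tied at the best distance
// <= max_mismatch are counted in n_best; one of them is reported, chosen
// uniformly at random via R's RNG so repeated identical segments do not all
// attract the same tie-broken reads.
//
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                        int seed_len, int max_mismatch) {
  std::vector<std::string> ctg(contigs.size());
  for (int i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  SeedIndex idx;
  build_index(ctg, seed_len, idx);

  std::vector<int> o_read, o_ctg, o_pos, o_mm, o_nbest;
  std::vector<int> o_strand; // 0 = +, 1 = -
  std::vector<int> o_qwidth;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    if (L < seed_len) continue;
    std::string rev = revcomp_str(fwd);
    int best = max_mismatch + 1;
    // candidate placements: strand, contig, pos
    std::vector<std::array<int64_t, 3> > best_loci;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      int offs[3] = {0, (L - seed_len) / 2, L - seed_len};
      std::vector<uint64_t> cand;
      for (int oi = 0; oi < 3; ++oi) {
        int off = offs[oi];
        if (oi > 0 && off == offs[oi - 1]) continue;
        uint64_t v;
        if (!encode_kmer(q.c_str() + off, seed_len, v)) continue;
        auto it = idx.map.find(v);
        if (it == idx.map.end()) continue;
        for (uint64_t packed : it->second) {
          int64_t ci = (int64_t)(packed >> 40);
          int64_t p = (int64_t)(packed & ((1ULL << 40) - 1)) - off;
          if (p < 0 || p + L > (int64_t)ctg[ci].size()) continue;
          cand.push_back(((uint64_t)ci << 40) | (uint64_t)p);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t packed : cand) {
        int64_t ci = (int64_t)(packed >> 40);
        int64_t p = (int64_t)(packed & ((1ULL << 40) - 1));
        int mm = hamming_capped(ctg[ci].c_str() + p, q.c_str(), L, best);
        if (mm < 0) continue;
        if (mm < best) {
          best = mm;
          best_loci.clear();
        }
        if (mm == best)
          best_loci.push_back({(int64_t)strand, ci, p});
      }
    }
    if (best > max_mismatch || best_loci.empty()) continue;
    int pick = 0;
    if (best_loci.size() > 1)
      pick = (int)(unif_rand() * best_loci.size());
    if (pick >= (int)best_loci.size()) pick = (int)best_loci.size() - 1;
    o_read.push_back(ri + 1);
    o_strand.push_back((int)best_loci[pick][0]);
    o_ctg.push_back((int)best_loci[pick][1] + 1);
    o_pos.push_back((int)best_loci[pick][2]);
    o_mm.push_back(best);
    o_nbest.push_back((int)best_loci.size());
    o_qwidth.push_back(L);
  }
  return DataFrame::create(
      _["read"] = o_read, _["contig"] = o_ctg, _["pos"] = o_pos,
      _["strand"] = o_strand, _["mismatches"] = o_mm,
      _["n_best"] = o_nbest, _["qwidth"] = o_qwidth);
}

// Brute-force oracle: scan every placement of every read on both strands of
// every contig, counting Hamming distance. Independent of the seed index.
// Returns, per read, the best distance (> max_mismatch reported as NA), the
// number of tied best placements, and whether the supplied candidate
// placement (1-based contig index, 0-based pos, strand 0/1) is among them.
//
// [[Rcpp::export]]
DataFrame cpp_scan_reads(CharacterVector reads, CharacterVector contigs,
                         int max_mismatch, IntegerVector cand_contig,
                         IntegerVector cand_pos, IntegerVector cand_strand) {
  std::vector<std::string> ctg(contigs.size());
  for (int i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  int n = reads.size();
  IntegerVector best_mm(n), n_best(n);
  LogicalVector cand_ok(n);
  for (int ri = 0; ri < n; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = revcomp_str(fwd);
    int L = (int)fwd.size();
    int best = max_mismatch + 1;
    long ties = 0;
    bool ok = false;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      for (size_t ci = 0; ci < ctg.size(); ++ci) {
        if ((int)ctg[ci].size() < L) continue;
        for (size_t p = 0; p + L <= ctg[ci].size(); ++p) {
          int mm = hamming_capped(ctg[ci].c_str() + p, q.c_str(), L, best);
          if (mm < 0) continue;
          if (mm < best) { best = mm; ties = 0; ok = false; }
          if (mm == best) {
            ++ties;
            if (cand_contig[ri] == (int)ci + 1 && cand_pos[ri] == (int)p &&
                cand_strand[ri] == strand)
              ok = true;
          }
        }
      }
    }
    if (best > max_mismatch) {
      best_mm[ri] = NA_INTEGER; n_best[ri] = 0; cand_ok[ri] = false;
    } else {
      best_mm[ri] = best; n_best[ri] = (int)ties; cand_ok[ri] = ok;
    }
  }
  return DataFrame::create(_["best_mm"] = best_mm, _["n_best"] = n_best,
                           _["cand_ok"] = cand_ok);
}

// Canonical k-mer multiplicity histogram: entry [d] = number of distinct
// canonical k-mers observed exactly d times (d = 1 .. max depth).
//
// [[Rcpp::export]]
IntegerVector cpp_kmer_histogram(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, int> counts;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string s = as<std::string>(reads[ri]);
    int L = (int)s.size();
    if (L < k) continue;
    // rolling forward and reverse-complement encodings
    uint64_t f = 0, r = 0;
    int valid = 0;
    for (int i = 0; i < L; ++i) {
      int c;
      switch (s[i]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { valid = 0; f = r = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid >= k) counts[f < r ? f : r]++;
    }
  }
  int maxd = 0;
  for (auto& kv : counts) maxd = std::max(maxd, kv.second);
  IntegerVector hist(maxd);
  for (auto& kv : counts) hist[kv.second - 1]++;
  return hist;
}
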