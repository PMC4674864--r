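// Core of the corrector: exact-keyed k-mer bucket index, candidate/neighbor
// discovery and the sequential weighted-consensus correction pass. The pass
// is fused in C++ because Step 2 (overlap + Hamming over every candidate
// pair) dominates the run time.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or anything else: no code
  }
}

struct Occ {
  int read;
  int pos;  // 0-based k-mer start within the read
};

typedef std::unordered_map<uint64_t, std::vector<Occ> > KIndex;

// Index every N-free k-mer occurrence; reads shorter than k contribute none.
static void build_index(const std::vector<std::string>& seqs, int k,
                        KIndex& idx) {
  const uint64_t mask =
      (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (size_t i = 0; i < seqs.size(); ++i) {
    const std::string& s = seqs[i];
    const int len = (int)s.size();
    if (len < k) continue;
    uint64_t key = 0;
    int valid = 0;  // length of the current run of unambiguous bases
    for (int j = 0; j < len; ++j) {
      const int c = base2code(s[j]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        Occ o; o.read = (int)i; o.pos = j - k + 1;
        idx[key].push_back(o);
      }
    }
  }
}

static std::string decode_kmer(uint64_t key, int k) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int j = k - 1; j >= 0; --j) {
    s[j] = b[key & 3ULL];
    key >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_kmer_index(CharacterVector seqs_, int k) {
  std::vector<std::string> seqs(seqs_.size());
  for (R_xlen_t i = 0; i < seqs_.size(); ++i) seqs[i] = as<std::string>(seqs_[i]);
  KIndex idx;
  build_index(seqs, k, idx);

  std::vector<uint64_t> keys;
  keys.reserve(idx.size());
  for (KIndex::const_iterator it = idx.begin(); it != idx.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());  // deterministic bucket order

  List out(keys.size());
  CharacterVector nms(keys.size());
  for (size_t b = 0; b < keys.size(); ++b) {
    const std::vector<Occ>& occ = idx[keys[b]];
    IntegerMatrix m(occ.size(), 2);
    for (size_t j = 0; j < occ.size(); ++j) {
      m(j, 0) = occ[j].read + 1;  // 1-based for R
      m(j, 1) = occ[j].pos + 1;
    }
    colnames(m) = CharacterVector::create("read", "pos");
    out[b] = m;
    nms[b] = decode_kmer(keys[b], k);
  }
  out.attr("names") = nms;
  return out;
}

// Hamming distance with the N-matches-nothing rule over the overlap given by
// `off` (neighbor position j aligns read position j + off; 0-based here).
static inline int overlap_mismatches(const std::string& a,
                                     const std::string& b, int off,
                                     int startA, int endA) {
  int mm = 0;
  for (int p = startA; p < endA; ++p) {
    const char x = a[p], y = b[p - off];
    if (x != y || x == 'N' || y == 'N') ++mm;
  }
  return mm;
}

struct Nbr {
  int read;
  int off;
};

// One full correction pass: index + candidates + true neighbors computed
// from the pass-start sequences, then sequential in-place consensus
// correction so later reads see earlier corrections and live perfect flags.
// [[Rcpp::export]]
List cpp_correct_pass(CharacterVector seqs_, LogicalVector perfect_, int k,
                      int min_overlap, int max_mismatch,
                      double perfect_weight, double min_support,
                      int bucket_cap) {
  const int n = (int)seqs_.size();
  std::vector<std::string> cur(n);
  for (int i = 0; i < n; ++i) cur[i] = as<std::string>(seqs_[i]);
  std::vector<char> perfect(n);
  for (int i = 0; i < n; ++i) perfect[i] = perfect_[i] ? 1 : 0;

  KIndex idx;
  build_index(cur, k, idx);

  // --- Step 1+2: per-read true-neighbor lists from pass-start sequences ---
  std::vector<std::vector<Nbr> > nbrs(n);
  {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    std::unordered_map<int, std::vector<int> > cand;  // neighbor -> offsets
    for (int i = 0; i < n; ++i) {
      cand.clear();
      const std::string& s = cur[i];
      const int len = (int)s.size();
      if (len >= k) {
        uint64_t key = 0;
        int valid = 0;
        for (int j = 0; j < len; ++j) {
          const int c = base2code(s[j]);
          if (c < 0) { valid = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)c) & mask;
          if (++valid < k) continue;
          const int p = j - k + 1;
          KIndex::const_iterator it = idx.find(key);
          if (it == idx.end()) continue;
          const std::vector<Occ>& bucket = it->second;
          if ((int)bucket.size() > bucket_cap) continue;
          for (size_t t = 0; t < bucket.size(); ++t) {
            if (bucket[t].read == i) continue;
            const int off = p - bucket[t].pos;
            std::vector<int>& offs = cand[bucket[t].read];
            if (std::find(offs.begin(), offs.end(), off) == offs.end())
              offs.push_back(off);
          }
        }
      }
      // best placement per candidate; keep if it passes the thresholds
      for (std::unordered_map<int, std::vector<int> >::iterator it =
               cand.begin();
           it != cand.end(); ++it) {
        const int jr = it->first;
        const std::string& t = cur[jr];
        const int lb = (int)t.size();
        int bestOff = 0, bestLen = -1, bestMM = 0;
        std::vector<int>& offs = it->second;
        std::sort(offs.begin(), offs.end());
        for (size_t u = 0; u < offs.size(); ++u) {
          const int off = offs[u];
          const int startA = std::max(0, off);
          const int endA = std::min(len, off + lb);
          const int olen = endA - startA;
          if (olen < 1) continue;
          const int mm = overlap_mismatches(s, t, off, startA, endA);
          bool better = false;
          if (olen > bestLen) better = true;
          else if (olen == bestLen) {
            if (mm < bestMM) better = true;
            else if (mm == bestMM && std::abs(off) < std::abs(bestOff))
              better = true;
          }
          if (better) { bestOff = off; bestLen = olen; bestMM = mm; }
        }
        if (bestLen >= min_overlap && bestMM <= max_mismatch) {
          Nbr nb; nb.read = jr; nb.off = bestOff;
          nbrs[i].push_back(nb);
        }
      }
      std::sort(nbrs[i].begin(), nbrs[i].end(),
                [](const Nbr& a, const Nbr& b) { return a.read < b.read; });
    }
  }

  // --- Step 3: sequential weighted-consensus correction, in input order ---
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  IntegerVector changes(n);
  std::vector<double> votes;
  for (int i = 0; i < n; ++i) {
    std::string& s = cur[i];
    const int len = (int)s.size();
    votes.assign((size_t)len * 4, 0.0);
    bool any_support = false;
    for (size_t u = 0; u < nbrs[i].size(); ++u) {
      const int jr = nbrs[i][u].read;
      const int off = nbrs[i][u].off;
      const double w = perfect[jr] ? perfect_weight : 1.0;  // live flag
      const std::string& t = cur[jr];                       // live sequence
      const int startA = std::max(0, off);
      const int endA = std::min(len, off + (int)t.size());
      for (int p = startA; p < endA; ++p) {
        const int c = base2code(t[p - off]);
        if (c >= 0) votes[(size_t)p * 4 + c] += w;
      }
    }
    int ch = 0;
    for (int p = 0; p < len; ++p) {
      const double* v = &votes[(size_t)p * 4];
      int best = 0;
      for (int c = 1; c < 4; ++c)
        if (v[c] > v[best]) best = c;  // ties keep the smaller code (A<C<G<T)
      const double bw = v[best];
      if (bw > 0.0) any_support = true;
      const int ic = base2code(s[p]);
      const double iw = (ic >= 0) ? v[ic] : 0.0;  // N holds no weight
      if (bw >= min_support && bw > iw) {
        s[p] = BASES[best];
        ++ch;
      }
    }
    changes[i] = ch;
    perfect[i] = (ch == 0 && any_support) ? 1 : 0;
  }

  CharacterVector outSeqs(n);
  LogicalVector outPerfect(n);
  for (int i = 0; i < n; ++i) {
    outSeqs[i] = cur[i];
    outPerfect[i] = perfect[i] != 0;
  }
  return List::create(_["seqs"] = outSeqs, _["perfect"] = outPerfect,
                      _["changes"] = changes);
}
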