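#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; returns 4 for anything not ACGT
static inline uint64_t base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// splitmix64 finalizer: well-mixed 64-bit hash of a k-mer code
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// canonical k-mer code (min of forward and reverse-complement codes), or
// UINT64_MAX if the window holds a non-ACGT character
static inline uint64_t canon_code(const char* s, int pos, int k) {
  uint64_t fwd = 0, rev = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t b = base2bit(s[pos + i]);
    if (b > 3) return UINT64_MAX;
    fwd = (fwd << 2) | b;
    rev |= (3 - b) << (2 * i);
  }
  return fwd < rev ? fwd : rev;
}

// Bottom-s MinHash sketch of the canonical k-mers of one sequence.
// Hashes are truncated to 53 bits so they survive the round-trip through
// R doubles exactly.
// [[Rcpp::export]]
NumericVector cpp_kmer_sketch(std::string seq, int k, int sketch_size) {
  int n = (int)seq.size() - k + 1;
  if (n < 1) stop("sequence shorter than k");
  std::unordered_set<uint64_t> seen;
  seen.reserve(n * 2);
  const char* s = seq.c_str();
  for (int p = 0; p < n; ++p) {
    uint64_t code = canon_code(s, p, k);
    if (code == UINT64_MAX) continue;
    seen.insert(mix64(code) >> 11);
  }
  std::vector<uint64_t> h(seen.begin(), seen.end());
  std::sort(h.begin(), h.end());
  int keep = std::min((int)h.size(), sketch_size);
  NumericVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = (double)h[i];
  return out;
}

// Mash-style Jaccard between two bottom sketches: scan the merged union in
// increasing hash order up to sketch_size distinct values, count shared.
// [[Rcpp::export]]
double cpp_sketch_jaccard(NumericVector h1, NumericVector h2, int sketch_size) {
  int i = 0, j = 0, uni = 0, shared = 0;
  int n1 = h1.size(), n2 = h2.size();
  while (uni < sketch_size && (i < n1 || j < n2)) {
    if (j >= n2 || (i < n1 && h1[i] < h2[j])) { ++i; }
    else if (i >= n1 || h2[j] < h1[i]) { ++j; }
    else { ++shared; ++i; ++j; }
    ++uni;
  }
  if (uni == 0) return 0.0;
  return (double)shared / (double)uni;
}

// Exact (unsketched) canonical k-mer Jaccard, for small-genome use
// [[Rcpp::export]]
double cpp_exact_kmer_jaccard(std::string seqA, std::string seqB, int k) {
  if ((int)seqA.size() < k || (int)seqB.size() < k) stop("sequence shorter than k");
  std::unordered_set<uint64_t> a, b;
  const char* sa = seqA.c_str();
  for (int p = 0; p <= (int)seqA.size() - k; ++p) {
    uint64_t c = canon_code(sa, p, k);
    if (c != UINT64_MAX) a.insert(c);
  }
  const char* sb = seqB.c_str();
  for (int p = 0; p <= (int)seqB.size() - k; ++p) {
    uint64_t c = canon_code(sb, p, k);
    if (c != UINT64_MAX) b.insert(c);
  }
  size_t shared = 0;
  for (uint64_t x : a) if (b.count(x)) ++shared;
  size_t uni = a.size() + b.size() - shared;
  if (uni == 0) return 0.0;
  return (double)shared / (double)uni;
}

// Substitution-only mutation of each sequence at the given per-base rate.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int nmut = (int)R::rbinom((double)L, rate);
    for (int m = 0; m < nmut; ++m) {
      int pos = (int)(unif_rand() * L);
      if (pos >= L) pos = L - 1;
      uint64_t old = base2bit(s[pos]);
      if (old > 3) continue;
      // choose one of the 3 other bases uniformly
      int shift = 1 + (int)(unif_rand() * 3);
      if (shift > 3) shift = 3;
      s[pos] = bases[(old + shift) % 4];
    }
    out[i] = s;
  }
  return out;
}

// Read recruitment against a marker database.
//
// Candidate markers are gathered by exact shared k-mers (seeds taken every
// `stride` bases along the read, last window always included), then for each
// candidate (marker, diagonal) the ungapped identity of the full read placed
// on that diagonal is computed; positions falling off the marker count as
// mismatches. A read is assigned to the species of its best-identity marker
// iff identity >= min_identity; equal best identity across two species
// discards the read.
//
// Returns per-read 1-based species index (0 = unassigned), family index and
// identity.
// [[Rcpp::export]]
List cpp_recruit(CharacterVector reads, CharacterVector markers,
                 IntegerVector marker_species, IntegerVector marker_family,
                 int k, double min_identity, int stride) {
  int nm = markers.size();
  if (nm == 0) stop("empty marker database");
  std::vector<std::string> mseq(nm);
  for (int m = 0; m < nm; ++m) mseq[m] = as<std::string>(markers[m]);

  // forward-strand k-mer index over markers: code -> (marker, pos)
  std::unordered_multimap<uint64_t, std::pair<int,int> > index;
  for (int m = 0; m < nm; ++m) {
    const char* s = mseq[m].c_str();
    int L = (int)mseq[m].size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t code = 0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        uint64_t b = base2bit(s[p + i]);
        if (b > 3) { ok = false; break; }
        code = (code << 2) | b;
      }
      if (ok) index.insert({code, {m, p}});
    }
  }

  int nr = reads.size();
  IntegerVector out_species(nr), out_family(nr);
  NumericVector out_identity(nr);
  std::vector<std::pair<int,int> > cands; // (marker, offset)
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const char* rs = rd.c_str();
    int L = (int)rd.size();
    if (L < k) { out_species[r] = 0; continue; }
    cands.clear();
    for (int p = 0; p + k <= L; p += stride) {
      int pp = (p + k > L) ? L - k : p;
      uint64_t code = 0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        uint64_t b = base2bit(rs[pp + i]);
        if (b > 3) { ok = false; break; }
        code = (code << 2) | b;
      }
      if (!ok) continue;
      auto range = index.equal_range(code);
      for (auto it = range.first; it != range.second; ++it)
        cands.push_back({it->second.first, it->second.second - pp});
    }
    // always also seed the final window
    if (L > k) {
      int pp = L - k;
      uint64_t code = 0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        uint64_t b = base2bit(rs[pp + i]);
        if (b > 3) { ok = false; break; }
        code = (code << 2) | b;
      }
      if (ok) {
        auto range = index.equal_range(code);
        for (auto it = range.first; it != range.second; ++it)
          cands.push_back({it->second.first, it->second.second - pp});
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    double best_id = -1.0;
    int best_marker = -1;
    bool tie_across_species = false;
    for (auto& cd : cands) {
      int m = cd.first, off = cd.second;
      const std::string& ms = mseq[m];
      int ML = (int)ms.size();
      int matches = 0;
      int lo = std::max(0, -off), hi = std::min(L, ML - off);
      for (int i = lo; i < hi; ++i) if (rs[i] == ms[off + i]) ++matches;
      double id = (double)matches / (double)L; // off-marker positions are mismatches
      if (id > best_id + 1e-12) {
        best_id = id; best_marker = m; tie_across_species = false;
      } else if (id > best_id - 1e-12 && best_marker >= 0 &&
                 marker_species[m] != marker_species[best_marker]) {
        tie_across_species = true;
      }
    }
    if (best_marker >= 0 && !tie_across_species && best_id >= min_identity) {
      out_species[r] = marker_species[best_marker];
      out_family[r] = marker_family[best_marker];
      out_identity[r] = best_id;
    } else {
      out_species[r] = 0;
      out_family[r] = 0;
      out_identity[r] = (best_marker >= 0) ? best_id : NA_REAL;
    }
  }
  return List::create(_["species"] = out_species,
                      _["family"] = out_family,
                      _["identity"] = out_identity);
}
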