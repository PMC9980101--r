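#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 64-bit finalizer used for seeded k-mer hashing (splitmix64 mixing constants)
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;  // N or anything else invalidates the window
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Canonical k-mer codes of every valid window (windows containing non-ACGT
// characters are skipped). k must be <= 31 so codes fit in 62 bits.
static std::vector<uint64_t> canon_codes(const std::string &seq, int k) {
  std::vector<uint64_t> out;
  int n = (int)seq.size();
  if (k < 1 || k > 31 || n < k) return out;
  out.reserve(n - k + 1);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  int shift = 2 * (k - 1);
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) {
      valid = 0;
      fwd = rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(std::string seq, int k) {
  std::vector<uint64_t> codes = canon_codes(seq, k);
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (size_t i = 0; i < codes.size(); ++i) {
    uint64_t c = codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[c & 3ULL];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Seeded hash values in [0, 1) of the canonical k-mers of seq, one per valid
// window. Used for bottom-s MinHash sketches.
// [[Rcpp::export]]
NumericVector canonical_kmer_hashes_cpp(std::string seq, int k, int seed) {
  std::vector<uint64_t> codes = canon_codes(seq, k);
  uint64_t sd = mix64((uint64_t)(uint32_t)seed);
  NumericVector out(codes.size());
  const double inv = 1.0 / 18446744073709551616.0;  // 2^-64
  for (size_t i = 0; i < codes.size(); ++i)
    out[i] = (double)mix64(codes[i] ^ sd) * inv;
  return out;
}

// One greedy optimization pass over merged sets of an Ising-form objective
//   O(sigma) = sum_{edges (i,j)} w_ij * sigma_i * sigma_j,  sigma in {-1,+1}.
// Sweeps the sets in a fresh random order (R RNG) and flips any set whose
// flip strictly increases the objective, until a full sweep makes no flip.
// Adjacency in CSR form with 0-based indices; sigma is modified and returned.
// [[Rcpp::export]]
IntegerVector greedy_sweep_cpp(IntegerVector sigma_in,
                               IntegerVector adj_start,
                               IntegerVector adj_idx,
                               NumericVector adj_w) {
  int n = sigma_in.size();
  IntegerVector sigma = clone(sigma_in);
  if (n == 0) return sigma;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  bool improved = true;
  while (improved) {
    improved = false;
    // Fisher-Yates shuffle from R's RNG so the visit order is seed-driven
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      double field = 0.0;
      for (int p = adj_start[i]; p < adj_start[i + 1]; ++p)
        field += adj_w[p] * sigma[adj_idx[p]];
      // flipping sigma_i changes the objective by -2 * sigma_i * field
      if (-2.0 * sigma[i] * field > 0.0) {
        sigma[i] = -sigma[i];
        improved = true;
      }
    }
  }
  return sigma;
}
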