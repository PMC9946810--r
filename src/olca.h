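#ifndef OLCA_H
#define OLCA_H

#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <cstring>
#include <vector>
#include <unordered_map>

// 2-bit DNA encoding: A=0, C=1, G=2, T=3, most-significant digit first.
static inline int olcaBaseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char OLCA_BASES[4] = {'A', 'C', 'G', 'T'};

// reverse complement of a 15-mer code (30 bits)
static inline uint32_t olcaRc15(uint32_t code) {
  uint32_t rc = 0;
  for (int i = 0; i < 15; i++) {
    rc = (rc << 2) | (3u - (code & 3u));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t olcaRcK(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; i++) {
    rc = (rc << 2) | (3ull - (code & 3ull));
    code >>= 2;
  }
  return rc;
}

// Fixed-size 15-mer count table: always 2^30 entries of 2 bytes, as in the
// spectrum contract. calloc keeps resident memory proportional to the pages
// actually touched while preserving the fixed-array semantics.
struct Spectrum15 {
  static const int K = 15;
  static const size_t NCODES = (size_t)1 << 30;
  static const uint16_t CAP = 32767;  // counters saturate at 2^15 - 1

  uint16_t* counts;
  std::vector<uint32_t> observed;  // codes whose count went 0 -> 1
  double instances;                // 15-mer instances scanned (each once)
  bool both;                       // both-strand counting vs canonical-only

  explicit Spectrum15(bool both_) : both(both_) {
    counts = (uint16_t*)std::calloc(NCODES, sizeof(uint16_t));
    if (!counts) Rcpp::stop("cannot allocate the 2^30-entry 15-mer spectrum array");
    instances = 0.0;
  }
  ~Spectrum15() { std::free(counts); }
  Spectrum15(const Spectrum15&) = delete;
  Spectrum15& operator=(const Spectrum15&) = delete;

  inline void bump(uint32_t code) {
    uint16_t& c = counts[code];
    if (c == 0) observed.push_back(code);
    if (c < CAP) c++;
  }

  void addSeq(const char* s, size_t n) {
    if (n < (size_t)K) return;
    const uint32_t mask = ((uint32_t)1 << 30) - 1;
    uint32_t fc = 0, rc = 0;
    int valid = 0;
    for (size_t i = 0; i < n; i++) {
      int b = olcaBaseCode(s[i]);
      if (b < 0) { valid = 0; fc = 0; rc = 0; continue; }
      fc = ((fc << 2) | (uint32_t)b) & mask;
      rc = (rc >> 2) | ((uint32_t)(3 - b) << (2 * (K - 1)));
      if (valid < K) valid++;
      if (valid >= K) {
        instances += 1.0;
        if (both) { bump(fc); bump(rc); }
        else bump(fc < rc ? fc : rc);
      }
    }
  }

  // count x for a 15-mer given as its forward code
  inline uint16_t countAt(uint32_t code) const {
    if (both) return counts[code];
    uint32_t rc = olcaRc15(code);
    return counts[code < rc ? code : rc];
  }
};

// Context for the rank-based hash h(b) = cumBelow(r(x)) + b mod primeAbove(x),
// where x is the spectrum count of the 15-mer suffix of the k-mer code b.
struct HashCtx {
  const Spectrum15* sp;
  int mode;
  const int* prime;      // prime[x], x in 0..CAP
  const double* cum;     // cum[r] = # distinct observed 15-mers with rank < r
  int cumLen;

  inline uint64_t hash(uint64_t b) const {
    uint32_t suffix = (uint32_t)(b & (((uint64_t)1 << 30) - 1));
    int x = sp->countAt(suffix);
    int r = 2 * std::abs(x - mode);
    if (r >= cumLen) r = cumLen - 1;
    return (uint64_t)cum[r] + (b % (uint64_t)prime[x]);
  }
};

struct MinItem {
  uint64_t hash;
  uint64_t code;  // code of the selected orientation
  int pos;        // 0-based start on the forward strand
  bool rev;       // selected orientation was the reverse complement
};

void olcaMinimizers(const char* s, size_t n, int k, int w, const HashCtx& ctx,
                    std::vector<MinItem>& out);

struct MTEntry {
  uint64_t code;
  int32_t seq;  // 0-based sequence index
  int32_t pos;
  uint8_t rev;
};

struct MinTable {
  std::unordered_map<uint64_t, std::vector<MTEntry>> map;
  int k, w;
  double maxFreq;
  double nEntries = 0, nPurged = 0;
};

#endif
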