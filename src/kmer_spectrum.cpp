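#include "olca.h"
#include <algorithm>
#include <map>
using namespace Rcpp;

// ---- k-mer encoding -------------------------------------------------------

static uint64_t encodeOrStop(const char* s, int k, bool* ok) {
  uint64_t b = 0;
  *ok = true;
  for (int i = 0; i < k; i++) {
    int c = olcaBaseCode(s[i]);
    if (c < 0) { *ok = false; return 0; }
    b = (b << 2) | (uint64_t)c;
  }
  return b;
}

static std::string decodeCode(uint64_t b, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = OLCA_BASES[b & 3ull];
    b >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector olca_encode_kmer(CharacterVector kmers, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)std::strlen(s) != k) stop("k-mer length does not match k");
    bool ok;
    uint64_t b = encodeOrStop(s, k, &ok);
    out[i] = ok ? (double)b : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector olca_decode_kmer(NumericVector codes, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    out[i] = decodeCode((uint64_t)codes[i], k);
  }
  return out;
}

// Full 64-bit encode -> decode round trip (exercises codes beyond double
// precision, e.g. k = 31).
// [[Rcpp::export]]
CharacterVector olca_kmer_roundtrip(CharacterVector kmers, int k) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    bool ok;
    uint64_t b = encodeOrStop(CHAR(STRING_ELT(kmers, i)), k, &ok);
    if (ok) out[i] = decodeCode(b, k);
    else out[i] = NA_STRING;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector olca_revcomp_code(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_REAL; continue; }
    out[i] = (double)olcaRcK((uint64_t)codes[i], k);
  }
  return out;
}

// Canonical k-mer codes (min of forward / reverse-complement code) at every
// N-free position; exact in doubles for k <= 26. pos is 0-based.
// [[Rcpp::export]]
DataFrame olca_kmer_codes_canonical(std::string seq, int k) {
  if (k < 1 || k > 26) stop("canonical code extraction supports k <= 26");
  const uint64_t mask = (k == 32) ? ~0ull : (((uint64_t)1 << (2 * k)) - 1);
  size_t n = seq.size();
  std::vector<double> codes;
  std::vector<int> poss;
  uint64_t fc = 0, rc = 0;
  int valid = 0;
  for (size_t i = 0; i < n; i++) {
    int b = olcaBaseCode(seq[i]);
    if (b < 0) { valid = 0; fc = 0; rc = 0; continue; }
    fc = ((fc << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (valid < k) valid++;
    if (valid >= k) {
      codes.push_back((double)(fc < rc ? fc : rc));
      poss.push_back((int)(i + 1 - k));
    }
  }
  return DataFrame::create(_["pos"] = poss, _["code"] = codes);
}

// [[Rcpp::export]]
CharacterVector olca_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = std::strlen(s);
    std::string r(len, 'N');
    for (size_t j = 0; j < len; j++) {
      char c = s[len - 1 - j];
      switch (c) {
        case 'A': case 'a': r[j] = 'T'; break;
        case 'C': case 'c': r[j] = 'G'; break;
        case 'G': case 'g': r[j] = 'C'; break;
        case 'T': case 't': r[j] = 'A'; break;
        default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// ---- spectrum -------------------------------------------------------------

// [[Rcpp::export]]
SEXP olca_spectrum_build(CharacterVector seqs, bool bothStrands) {
  XPtr<Spectrum15> p(new Spectrum15(bothStrands), true);
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    p->addSeq(s, std::strlen(s));
  }
  return p;
}

// [[Rcpp::export]]
List olca_spectrum_info(SEXP sp) {
  XPtr<Spectrum15> p(sp);
  return List::create(_["instances"] = p->instances,
                      _["nObserved"] = (double)p->observed.size(),
                      _["both"] = p->both);
}

// histogram: count value -> number of distinct 15-mers with that count
// [[Rcpp::export]]
DataFrame olca_spectrum_histogram(SEXP sp) {
  XPtr<Spectrum15> p(sp);
  std::map<int, double> h;
  for (uint32_t code : p->observed) h[p->counts[code]] += 1.0;
  std::vector<int> cnt;
  std::vector<double> dst;
  for (auto& kv : h) { cnt.push_back(kv.first); dst.push_back(kv.second); }
  return DataFrame::create(_["count"] = cnt, _["distinct"] = dst);
}

// counts for 15-mers given as forward codes
// [[Rcpp::export]]
IntegerVector olca_spectrum_counts(SEXP sp, NumericVector codes) {
  XPtr<Spectrum15> p(sp);
  R_xlen_t n = codes.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_INTEGER; continue; }
    out[i] = p->countAt((uint32_t)codes[i]);
  }
  return out;
}

// distinct observed 15-mer codes (forward or canonical depending on policy)
// [[Rcpp::export]]
NumericVector olca_spectrum_observed(SEXP sp) {
  XPtr<Spectrum15> p(sp);
  NumericVector out(p->observed.size());
  for (size_t i = 0; i < p->observed.size(); i++) out[i] = (double)p->observed[i];
  return out;
}

// ---- rank model -----------------------------------------------------------

// primeAbove[x] = smallest prime > x, for x in 0..CAP;
// cumByRank[r + 1] ... cum[r] = number of distinct observed 15-mers with rank < r
// [[Rcpp::export]]
List olca_rank_tables(SEXP sp, int mode) {
  XPtr<Spectrum15> p(sp);
  const int CAP = Spectrum15::CAP;

  // sieve up to the first prime above CAP (32771)
  const int SMAX = CAP + 64;
  std::vector<bool> comp(SMAX + 1, false);
  for (int i = 2; (long)i * i <= SMAX; i++)
    if (!comp[i])
      for (int j = i * i; j <= SMAX; j += i) comp[j] = true;
  IntegerVector prime(CAP + 1);
  for (int x = 0; x <= CAP; x++) {
    int q = std::max(2, x + 1);
    while (q <= SMAX && comp[q]) q++;
    prime[x] = q;
  }

  const int RMAX = 2 * CAP + 2;
  std::vector<double> atRank(RMAX + 1, 0.0);
  for (uint32_t code : p->observed) {
    int x = p->counts[code];
    int r = 2 * std::abs(x - mode);
    if (r > RMAX) r = RMAX;
    atRank[r] += 1.0;
  }
  NumericVector cum(RMAX + 2);
  cum[0] = 0.0;
  for (int r = 1; r <= RMAX + 1; r++) cum[r] = cum[r - 1] + atRank[r - 1];

  return List::create(_["primeAbove"] = prime, _["cumByRank"] = cum);
}

// forward-strand hash of every N-free k-mer of seq (test / diagnostic surface)
// [[Rcpp::export]]
DataFrame olca_hash_kmers(SEXP sp, int mode, IntegerVector primeAbove,
                          NumericVector cumByRank, std::string seq, int k) {
  if (k < 15 || k > 31) stop("hashing requires 15 <= k <= 31");
  XPtr<Spectrum15> p(sp);
  HashCtx ctx{p.get(), mode, INTEGER(primeAbove), REAL(cumByRank),
              (int)cumByRank.size()};
  const uint64_t mask = (((uint64_t)1) << (2 * k)) - 1;
  size_t n = seq.size();
  std::vector<int> poss, cnts;
  std::vector<double> hashes, codes;
  uint64_t fc = 0;
  int valid = 0;
  for (size_t i = 0; i < n; i++) {
    int b = olcaBaseCode(seq[i]);
    if (b < 0) { valid = 0; fc = 0; continue; }
    fc = ((fc << 2) | (uint64_t)b) & mask;
    if (valid < k) valid++;
    if (valid >= k) {
      poss.push_back((int)(i + 1 - k));
      codes.push_back((double)fc);
      hashes.push_back((double)ctx.hash(fc));
      cnts.push_back(p->countAt((uint32_t)(fc & (((uint64_t)1 << 30) - 1))));
    }
  }
  return DataFrame::create(_["pos"] = poss, _["code"] = codes,
                           _["hash"] = hashes, _["suffixCount"] = cnts);
}

// ---- substitution error correction ---------------------------------------

// A position is weak when every overlapping 15-mer has count < minSolid; a
// single substitution is accepted when it is the unique base change lifting
// all overlapping 15-mers to >= minSolid.
// [[Rcpp::export]]
std::string olca_correct_read(SEXP sp, std::string seq, int minSolid) {
  XPtr<Spectrum15> p(sp);
  const int K = 15;
  int n = (int)seq.size();
  if (n < K) return seq;

  auto kmerCountAt = [&](int pos) -> int {
    // count of 15-mer starting at pos; -1 if it contains a non-ACGT base
    uint32_t fc = 0;
    for (int i = pos; i < pos + K; i++) {
      int b = olcaBaseCode(seq[i]);
      if (b < 0) return -1;
      fc = (fc << 2) | (uint32_t)b;
    }
    return p->countAt(fc);
  };

  auto allSolidAround = [&](int pos) -> bool {
    int lo = std::max(0, pos - K + 1), hi = std::min(pos, n - K);
    for (int s = lo; s <= hi; s++) {
      int c = kmerCountAt(s);
      if (c >= 0 && c >= minSolid) return true;  // one solid k-mer clears it
    }
    return false;
  };

  auto allCovering = [&](int pos, int thr) -> bool {
    // true when every valid 15-mer covering pos has count >= thr
    int lo = std::max(0, pos - K + 1), hi = std::min(pos, n - K);
    bool any = false;
    for (int s = lo; s <= hi; s++) {
      int c = kmerCountAt(s);
      if (c < 0) continue;
      any = true;
      if (c < thr) return false;
    }
    return any;
  };

  for (int pos = 0; pos < n; pos++) {
    char orig = seq[pos];
    if (olcaBaseCode(orig) < 0) continue;
    if (allSolidAround(pos)) continue;  // some covering k-mer already solid
    int accepted = -1;
    int nAccepted = 0;
    for (int b = 0; b < 4; b++) {
      if (OLCA_BASES[b] == orig) continue;
      seq[pos] = OLCA_BASES[b];
      if (allCovering(pos, minSolid)) { accepted = b; nAccepted++; }
    }
    if (nAccepted == 1) seq[pos] = OLCA_BASES[accepted];
    else seq[pos] = orig;
  }
  return seq;
}
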