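#include "olca.h"
#include <deque>
using namespace Rcpp;

// (hash, code, pos)-lexicographic comparison; determinism under ties
static inline bool minLess(const MinItem& a, const MinItem& b) {
  if (a.hash != b.hash) return a.hash < b.hash;
  if (a.code != b.code) return a.code < b.code;
  return a.pos < b.pos;
}

// Standard minimizer scheme over the rank-based hash: the minimum-hash k-mer
// of every window of w consecutive k-mer positions is emitted once. The
// orientation with the smaller hash (ties: smaller code) is selected, which
// makes the scheme strand-symmetric. k-mers containing N are skipped.
void olcaMinimizers(const char* s, size_t n, int k, int w, const HashCtx& ctx,
                    std::vector<MinItem>& out) {
  if (n < (size_t)(k + w - 1)) return;
  const uint64_t mask = (((uint64_t)1) << (2 * k)) - 1;
  uint64_t fc = 0, rc = 0;
  int valid = 0;
  std::deque<MinItem> dq;
  int lastEmitted = -1;
  for (size_t i = 0; i < n; i++) {
    int b = olcaBaseCode(s[i]);
    if (b < 0) { valid = 0; fc = 0; rc = 0; }
    else {
      fc = ((fc << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (valid < k) valid++;
    }
    if ((int)i < k - 1) continue;
    int pos = (int)i - k + 1;  // k-mer start position
    // drop candidates that left the window [pos - w + 1, pos]
    while (!dq.empty() && dq.front().pos < pos - w + 1) dq.pop_front();
    if (b >= 0 && valid >= k) {
      MinItem it;
      uint64_t hf = ctx.hash(fc), hr = ctx.hash(rc);
      if (hf < hr || (hf == hr && fc <= rc)) it = MinItem{hf, fc, pos, false};
      else it = MinItem{hr, rc, pos, true};
      while (!dq.empty() && minLess(it, dq.back())) dq.pop_back();
      dq.push_back(it);
    }
    if (pos >= w - 1 && !dq.empty() && dq.front().pos != lastEmitted) {
      out.push_back(dq.front());
      lastEmitted = dq.front().pos;
    }
  }
}

// [[Rcpp::export]]
DataFrame olca_minimizers(SEXP sp, int mode, IntegerVector primeAbove,
                          NumericVector cumByRank, std::string seq, int k, int w) {
  if (k < 15 || k > 31) stop("minimizers require 15 <= k <= 31");
  if (w < 1) stop("w must be >= 1");
  XPtr<Spectrum15> p(sp);
  HashCtx ctx{p.get(), mode, INTEGER(primeAbove), REAL(cumByRank),
              (int)cumByRank.size()};
  std::vector<MinItem> items;
  olcaMinimizers(seq.c_str(), seq.size(), k, w, ctx, items);
  size_t n = items.size();
  IntegerVector pos(n);
  NumericVector hash(n), code(n);
  LogicalVector rev(n);
  for (size_t i = 0; i < n; i++) {
    pos[i] = items[i].pos;
    hash[i] = (double)items[i].hash;
    code[i] = (double)items[i].code;
    rev[i] = items[i].rev;
  }
  return DataFrame::create(_["pos"] = pos, _["hash"] = hash, _["code"] = code,
                           _["reverse"] = rev);
}

// ---- minimizer table ------------------------------------------------------

// [[Rcpp::export]]
SEXP olca_table_new(int k, int w, double maxFreq) {
  MinTable* t = new MinTable();
  t->k = k; t->w = w; t->maxFreq = maxFreq;
  return XPtr<MinTable>(t, true);
}

// [[Rcpp::export]]
void olca_table_insert(SEXP tab, SEXP sp, int mode, IntegerVector primeAbove,
                       NumericVector cumByRank, std::string seq, int seqId0) {
  XPtr<MinTable> t(tab);
  XPtr<Spectrum15> p(sp);
  HashCtx ctx{p.get(), mode, INTEGER(primeAbove), REAL(cumByRank),
              (int)cumByRank.size()};
  std::vector<MinItem> items;
  olcaMinimizers(seq.c_str(), seq.size(), t->k, t->w, ctx, items);
  for (const MinItem& it : items) {
    t->map[it.code].push_back(MTEntry{it.code, (int32_t)seqId0, (int32_t)it.pos,
                                      (uint8_t)it.rev});
    t->nEntries += 1;
  }
}

// purge minimizers whose occurrence count reaches maxFreq
// [[Rcpp::export]]
void olca_table_finalize(SEXP tab) {
  XPtr<MinTable> t(tab);
  if (!R_finite(t->maxFreq)) return;
  for (auto it = t->map.begin(); it != t->map.end();) {
    if ((double)it->second.size() >= t->maxFreq) {
      t->nEntries -= (double)it->second.size();
      t->nPurged += (double)it->second.size();
      it = t->map.erase(it);
    } else ++it;
  }
}

// [[Rcpp::export]]
List olca_table_stats(SEXP tab) {
  XPtr<MinTable> t(tab);
  return List::create(_["nMinimizers"] = (double)t->map.size(),
                      _["nEntries"] = t->nEntries, _["nPurged"] = t->nPurged,
                      _["k"] = t->k, _["w"] = t->w, _["maxFreq"] = t->maxFreq);
}

// Query: the table is keyed by the minimizer k-mer code (exact matching; the
// hash only drives minimizer selection). reverse = TRUE when query and
// subject selected opposite orientations.
// [[Rcpp::export]]
DataFrame olca_table_query(SEXP tab, SEXP sp, int mode, IntegerVector primeAbove,
                           NumericVector cumByRank, std::string seq) {
  XPtr<MinTable> t(tab);
  XPtr<Spectrum15> p(sp);
  HashCtx ctx{p.get(), mode, INTEGER(primeAbove), REAL(cumByRank),
              (int)cumByRank.size()};
  std::vector<MinItem> items;
  olcaMinimizers(seq.c_str(), seq.size(), t->k, t->w, ctx, items);
  std::vector<int> subj, spos, qpos;
  std::vector<bool> rev;
  for (const MinItem& it : items) {
    auto f = t->map.find(it.code);
    if (f == t->map.end()) continue;
    for (const MTEntry& e : f->second) {
      subj.push_back(e.seq + 1);  // 1-based for R
      spos.push_back(e.pos);
      qpos.push_back(it.pos);
      rev.push_back(((bool)e.rev) != it.rev);
    }
  }
  return DataFrame::create(_["subject"] = subj, _["subjectPos"] = spos,
                           _["queryPos"] = qpos, _["reverse"] = rev);
}

// Incremental all-vs-longer scan: sequences must be ordered by decreasing
// length; each sequence is queried against the table of the (longer)
// sequences before it, then inserted. Returns all raw hits.
// [[Rcpp::export]]
DataFrame olca_overlap_candidates(SEXP sp, int mode, IntegerVector primeAbove,
                                  NumericVector cumByRank, CharacterVector seqs,
                                  int k, int w) {
  XPtr<Spectrum15> p(sp);
  HashCtx ctx{p.get(), mode, INTEGER(primeAbove), REAL(cumByRank),
              (int)cumByRank.size()};
  MinTable t;
  t.k = k; t.w = w; t.maxFreq = R_PosInf;
  std::vector<int> qry, subj, spos, qpos;
  std::vector<bool> rev;
  std::vector<MinItem> items;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = std::strlen(s);
    items.clear();
    olcaMinimizers(s, n, k, w, ctx, items);
    for (const MinItem& it : items) {
      auto f = t.map.find(it.code);
      if (f == t.map.end()) continue;
      for (const MTEntry& e : f->second) {
        qry.push_back((int)i + 1);
        subj.push_back(e.seq + 1);
        spos.push_back(e.pos);
        qpos.push_back(it.pos);
        rev.push_back(((bool)e.rev) != it.rev);
      }
    }
    for (const MinItem& it : items)
      t.map[it.code].push_back(
          MTEntry{it.code, (int32_t)i, (int32_t)it.pos, (uint8_t)it.rev});
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["query"] = qry, _["subject"] = subj,
                           _["queryPos"] = qpos, _["subjectPos"] = spos,
                           _["reverse"] = rev);
}
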