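#include "olca.h"
#include <algorithm>
using namespace Rcpp;

static const int MATCH = 2, MISMATCH = -3, GAP = -4;
static const int NEG = -1000000000;

// ---- end-overlap alignment -------------------------------------------------
// Aligns a suffix of `a` (consensus tail) to a prefix of `b` (next read),
// banded around the expected overlap. Free start anywhere on `a`; the
// alignment must reach the end of `a`; the end on `b` is free.
// [[Rcpp::export]]
List olca_end_overlap(std::string a, std::string b, int expOverlap, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0)
    return List::create(_["overlapA"] = 0, _["bUsed"] = 0, _["matches"] = 0,
                        _["alnLen"] = 0, _["identity"] = 0.0, _["score"] = NEG);
  if (expOverlap < 0) expOverlap = 0;
  if (expOverlap > la) expOverlap = la;
  const int sA = la - expOverlap;  // expected start row on a
  const int width = 2 * band + 1;

  std::vector<int> prev(width, NEG), cur(width, NEG);
  std::vector<uint8_t> moves((size_t)(la + 1) * width, 0);
  auto origin = [&](int i) { return i - sA - band; };

  for (int i = 0; i <= la; i++) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int org = origin(i), orgPrev = origin(i - 1);
    int jlo = std::max(1, org), jhi = std::min(lb, org + 2 * band);
    for (int j = jlo; j <= jhi; j++) {
      const int idx = j - org;
      int best = NEG;
      uint8_t mv = 0;
      if (i >= 1) {
        // diagonal: D[i-1][j-1]
        int dprev = (j == 1) ? 0 : NEG;
        int pidx = (j - 1) - orgPrev;
        if (j >= 2 && pidx >= 0 && pidx < width && prev[pidx] > dprev)
          dprev = prev[pidx];
        if (j == 1 || (pidx >= 0 && pidx < width)) {
          int s = dprev + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
          if (dprev > NEG / 2 && s > best) { best = s; mv = 1; }
        }
        // up: D[i-1][j]
        int uidx = j - orgPrev;
        if (uidx >= 0 && uidx < width && prev[uidx] > NEG / 2) {
          int s = prev[uidx] + GAP;
          if (s > best) { best = s; mv = 2; }
        }
      }
      // left: D[i][j-1] (D[i][0] == 0, free start)
      int lval = (j == 1) ? 0 : ((idx - 1 >= 0) ? cur[idx - 1] : NEG);
      if (lval > NEG / 2) {
        int s = lval + GAP;
        if (s > best) { best = s; mv = 3; }
      }
      cur[idx] = best;
      moves[(size_t)i * width + idx] = mv;
    }
    std::swap(prev, cur);
  }

  // best end on the final row
  const int orgLast = origin(la);
  int bestScore = NEG, bestJ = -1;
  for (int j = std::max(1, orgLast); j <= std::min(lb, orgLast + 2 * band); j++) {
    int v = prev[j - orgLast];
    if (v > bestScore) { bestScore = v; bestJ = j; }
  }
  if (bestJ < 0 || bestScore <= NEG / 2)
    return List::create(_["overlapA"] = 0, _["bUsed"] = 0, _["matches"] = 0,
                        _["alnLen"] = 0, _["identity"] = 0.0, _["score"] = NEG);

  // traceback
  int i = la, j = bestJ, matches = 0, alnLen = 0;
  while (j > 0 && i >= 0) {
    uint8_t mv = moves[(size_t)i * width + (j - origin(i))];
    if (mv == 0) break;
    alnLen++;
    if (mv == 1) { if (a[i - 1] == b[j - 1]) matches++; i--; j--; }
    else if (mv == 2) i--;
    else j--;
  }
  double identity = alnLen > 0 ? (double)matches / alnLen : 0.0;
  return List::create(_["overlapA"] = la - i, _["bUsed"] = bestJ,
                      _["matches"] = matches, _["alnLen"] = alnLen,
                      _["identity"] = identity, _["score"] = bestScore);
}

// ---- glocal alignment ------------------------------------------------------
// The read is aligned end-to-end against a window of the contig; both ends on
// the window are free. `off` is the expected start of the read within the
// window. Returns 0-based start and M/X/I/D run-length ops.
// [[Rcpp::export]]
List olca_glocal(std::string read, std::string window, int off, int band) {
  const int lr = (int)read.size(), lw = (int)window.size();
  if (lr == 0 || lw == 0) stop("empty sequence in glocal alignment");
  const int width = 2 * band + 1;
  std::vector<int> prev(width, NEG), cur(width, NEG);
  std::vector<uint8_t> moves((size_t)(lr + 1) * width, 0);
  auto origin = [&](int i) { return i + off - band; };

  { // row 0: free start
    const int org = origin(0);
    for (int j = std::max(0, org); j <= std::min(lw, org + 2 * band); j++)
      prev[j - org] = 0;
  }
  for (int i = 1; i <= lr; i++) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int org = origin(i), orgPrev = origin(i - 1);
    int jlo = std::max(0, org), jhi = std::min(lw, org + 2 * band);
    for (int j = jlo; j <= jhi; j++) {
      const int idx = j - org;
      int best = NEG;
      uint8_t mv = 0;
      if (j >= 1) {
        int pidx = (j - 1) - orgPrev;
        if (pidx >= 0 && pidx < width && prev[pidx] > NEG / 2) {
          int s = prev[pidx] + (read[i - 1] == window[j - 1] ? MATCH : MISMATCH);
          if (s > best) { best = s; mv = 1; }
        }
      }
      int uidx = j - orgPrev;
      if (uidx >= 0 && uidx < width && prev[uidx] > NEG / 2) {
        int s = prev[uidx] + GAP;
        if (s > best) { best = s; mv = 2; }
      }
      if (idx - 1 >= 0 && cur[idx - 1] > NEG / 2) {
        int s = cur[idx - 1] + GAP;
        if (s > best) { best = s; mv = 3; }
      }
      cur[idx] = best;
      moves[(size_t)i * width + idx] = mv;
    }
    std::swap(prev, cur);
  }

  const int orgLast = origin(lr);
  int bestScore = NEG, bestJ = -1;
  for (int j = std::max(0, orgLast); j <= std::min(lw, orgLast + 2 * band); j++) {
    int v = prev[j - orgLast];
    if (v > bestScore) { bestScore = v; bestJ = j; }
  }
  if (bestJ < 0 || bestScore <= NEG / 2)
    return List::create(_["ok"] = false);

  // traceback, collecting run-length ops (0=M, 1=X, 2=I, 3=D)
  std::vector<int> rops, rlens;
  int i = lr, j = bestJ, matches = 0, alnLen = 0;
  auto pushOp = [&](int op) {
    if (!rops.empty() && rops.back() == op) rlens.back()++;
    else { rops.push_back(op); rlens.push_back(1); }
  };
  while (i > 0) {
    uint8_t mv = moves[(size_t)i * width + (j - origin(i))];
    if (mv == 0) break;
    alnLen++;
    if (mv == 1) {
      bool m = read[i - 1] == window[j - 1];
      if (m) matches++;
      pushOp(m ? 0 : 1);
      i--; j--;
    } else if (mv == 2) { pushOp(2); i--; }
    else { pushOp(3); j--; }
  }
  std::reverse(rops.begin(), rops.end());
  std::reverse(rlens.begin(), rlens.end());
  double identity = alnLen > 0 ? (double)matches / alnLen : 0.0;
  return List::create(_["ok"] = true, _["start"] = j,
                      _["ops"] = IntegerVector(rops.begin(), rops.end()),
                      _["lens"] = IntegerVector(rlens.begin(), rlens.end()),
                      _["matches"] = matches, _["alnLen"] = alnLen,
                      _["identity"] = identity, _["score"] = bestScore);
}

// ---- banded edit distance --------------------------------------------------
// [[Rcpp::export]]
double olca_banded_edit(std::string a, std::string b, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  const int W = std::max(band, 8) + std::abs(la - lb);
  const int width = 2 * W + 1;
  const int INF = 1000000000;
  std::vector<int> prev(width, INF), cur(width, INF);
  // row 0: D[0][j] = j, offset index = j - 0 + W
  for (int j = 0; j <= std::min(lb, W); j++) prev[j + W] = j;
  for (int i = 1; i <= la; i++) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(0, i - W), jhi = std::min(lb, i + W);
    for (int j = jlo; j <= jhi; j++) {
      int idx = j - i + W;
      int best = INF;
      if (j == 0) best = i;
      else {
        int d = prev[idx];  // (i-1, j-1)
        if (d < INF) best = std::min(best, d + (a[i - 1] != b[j - 1] ? 1 : 0));
        if (idx + 1 < width && prev[idx + 1] < INF)
          best = std::min(best, prev[idx + 1] + 1);  // (i-1, j)
        if (idx - 1 >= 0 && cur[idx - 1] < INF)
          best = std::min(best, cur[idx - 1] + 1);  // (i, j-1)
      }
      cur[idx] = best;
    }
    std::swap(prev, cur);
  }
  int idx = lb - la + W;
  if (idx < 0 || idx >= width || prev[idx] >= 1000000000) return NA_REAL;
  return prev[idx];
}

// ---- pileup ----------------------------------------------------------------
// counts: 4 x L base counts from M/X columns; ins/del: number of reads
// reporting an insertion / deletion at each column.
// [[Rcpp::export]]
List olca_pileup(int contigLen, IntegerVector starts, CharacterVector seqs,
                 List opsList, List lensList) {
  IntegerMatrix counts(4, contigLen);
  IntegerVector ins(contigLen), del(contigLen), depth(contigLen);
  for (R_xlen_t r = 0; r < starts.size(); r++) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    IntegerVector ops = opsList[r], lens = lensList[r];
    int cpos = starts[r], rpos = 0;
    for (R_xlen_t o = 0; o < ops.size(); o++) {
      int op = ops[o], len = lens[o];
      if (op == 0 || op == 1) {  // M / X
        for (int t = 0; t < len; t++) {
          if (cpos >= 0 && cpos < contigLen) {
            int b = olcaBaseCode(s[rpos]);
            if (b >= 0) counts(b, cpos)++;
            depth[cpos]++;
          }
          cpos++; rpos++;
        }
      } else if (op == 2) {  // insertion relative to contig
        int c = std::min(std::max(cpos, 0), contigLen - 1);
        ins[c]++;
        rpos += len;
      } else {  // deletion: every deleted column carries the call
        for (int t = 0; t < len; t++) {
          if (cpos >= 0 && cpos < contigLen) del[cpos]++;
          cpos++;
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["ins"] = ins, _["del"] = del,
                      _["depth"] = depth);
}

// ---- read bases at given contig positions ----------------------------------
// positions must be sorted ascending (0-based contig coordinates). Returns one
// row per (read, position) pair where the read has an aligned base (M/X).
// [[Rcpp::export]]
DataFrame olca_read_bases_at(IntegerVector starts, CharacterVector seqs,
                             List opsList, List lensList,
                             IntegerVector positions) {
  std::vector<int> outRead, outPos, outBase;
  const int np = (int)positions.size();
  for (R_xlen_t r = 0; r < starts.size(); r++) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    IntegerVector ops = opsList[r], lens = lensList[r];
    int cpos = starts[r], rpos = 0;
    // first position index >= cpos
    int pi = (int)(std::lower_bound(positions.begin(), positions.end(), cpos) -
                   positions.begin());
    for (R_xlen_t o = 0; o < ops.size() && pi < np; o++) {
      int op = ops[o], len = lens[o];
      if (op == 0 || op == 1) {
        int cend = cpos + len;
        while (pi < np && positions[pi] < cend) {
          if (positions[pi] >= cpos) {
            outRead.push_back((int)r + 1);
            outPos.push_back(pi + 1);
            outBase.push_back(olcaBaseCode(s[rpos + (positions[pi] - cpos)]));
          }
          pi++;
        }
        cpos = cend; rpos += len;
      } else if (op == 2) rpos += len;
      else {
        int cend = cpos + len;
        while (pi < np && positions[pi] < cend) pi++;  // deleted: no base
        cpos = cend;
      }
    }
  }
  return DataFrame::create(_["read"] = outRead, _["posIdx"] = outPos,
                           _["base"] = outBase);
}
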