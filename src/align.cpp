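#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global affine-gap alignment (Needleman-Wunsch / Gotoh three-state DP) with
// an optional diagonal band. A gap of length k scores gap_open + (k-1) *
// gap_extend. 'N' aligned against anything scores 0 (neither match nor
// mismatch). Tie-breaking is deterministic: at equal score a substitution
// column is preferred over a gap column, and a gap in the second row
// (consuming the first sequence, state X) over a gap in the first row
// (state Y); within a gap state, opening from the match state is preferred
// over extending at equal score.
//
// Score storage is two rolling rows; the traceback keeps one byte per state
// per banded cell, so memory is O(n * band) bytes. With band >= max(n, m)
// the search is exhaustive and the result is the optimal global alignment;
// a finite band returns the optimum among alignments whose path stays
// within the band around the main diagonal.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_extend,
               int band) {
  const long n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const long W = 2L * (long)band + 1L;

  auto center = [&](long i) -> long {
    return (long)(((double)i * (double)m) / (double)n + 0.5);
  };

  std::vector<double> Mp(W, NEG_INF), Xp(W, NEG_INF), Yp(W, NEG_INF);
  std::vector<double> Mc(W, NEG_INF), Xc(W, NEG_INF), Yc(W, NEG_INF);
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  // row 0: offsets o = j - (center(0) - band) = j - (0 - band) = j + band
  long c_prev = center(0);
  long lo_prev = std::max(0L, c_prev - band);
  long hi_prev = std::min(m, c_prev + band);
  long omin_prev = lo_prev - (c_prev - band), omax_prev = hi_prev - (c_prev - band);
  {
    long o0 = 0 - (c_prev - band);
    if (o0 < 0 || o0 >= W) stop("band excludes origin");
    Mp[o0] = 0.0;
    for (long j = std::max(1L, lo_prev); j <= hi_prev; ++j) {
      long o = j - (c_prev - band);
      Yp[o] = gap_open + (double)(j - 1) * gap_extend;
      tY[o] = (j == 1) ? 1 : 3;
    }
  }

  for (long i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Xc.begin(), Xc.end(), NEG_INF);
    std::fill(Yc.begin(), Yc.end(), NEG_INF);
    const long c_cur = center(i);
    const long lo = std::max(0L, c_cur - band);
    const long hi = std::min(m, c_cur + band);
    const long base = c_cur - band;           // j = o + base
    const long d = c_cur - c_prev;            // prev-row offset = o + d
    unsigned char *tMr = &tM[i * W], *tXr = &tX[i * W], *tYr = &tY[i * W];
    const char ca = a[i - 1];
    for (long j = lo; j <= hi; ++j) {
      const long o = j - base;
      const long op = o + d;                  // (i-1, j) in prev-row offsets
      const bool up_ok = op >= omin_prev && op <= omax_prev;
      const bool diag_ok = (op - 1) >= omin_prev && (op - 1) <= omax_prev;
      // X: gap in b, consume a[i-1]
      {
        double fromM = (up_ok ? Mp[op] : NEG_INF) + gap_open;
        double fromX = (up_ok ? Xp[op] : NEG_INF) + gap_extend;
        if (fromM >= fromX) { Xc[o] = fromM; tXr[o] = 1; }
        else { Xc[o] = fromX; tXr[o] = 2; }
      }
      if (j >= 1) {
        // Y: gap in a, consume b[j-1] (same output row)
        double fromM = (o >= 1 ? Mc[o - 1] : NEG_INF) + gap_open;
        double fromY = (o >= 1 ? Yc[o - 1] : NEG_INF) + gap_extend;
        if (fromM >= fromY) { Yc[o] = fromM; tYr[o] = 1; }
        else { Yc[o] = fromY; tYr[o] = 3; }
        // M: consume both
        const char cb = b[j - 1];
        double s = (ca == 'N' || cb == 'N') ? 0.0 : (ca == cb ? match : mismatch);
        double dM = diag_ok ? Mp[op - 1] : NEG_INF;
        double dX = diag_ok ? Xp[op - 1] : NEG_INF;
        double dY = diag_ok ? Yp[op - 1] : NEG_INF;
        double best = dM; unsigned char t = 0;
        if (dX > best) { best = dX; t = 2; }
        if (dY > best) { best = dY; t = 3; }
        if (best > NEG_INF / 2) { Mc[o] = best + s; tMr[o] = t; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    c_prev = c_cur;
    omin_prev = lo - base;
    omax_prev = hi - base;
  }

  const long base_n = center(n) - band;
  const long o_end = m - base_n;
  if (o_end < omin_prev || o_end > omax_prev)
    stop("band excludes terminal cell; increase band");
  double sM = Mp[o_end], sX = Xp[o_end], sY = Yp[o_end];
  int state; double score;
  if (sM >= sX && sM >= sY) { state = 0; score = sM; }
  else if (sX >= sY) { state = 1; score = sX; }
  else { state = 2; score = sY; }
  if (score < NEG_INF / 2) stop("no alignment within band; increase band");

  std::string ga, gb;
  long i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    const size_t q = (size_t)(i * W + (j - (center(i) - band)));
    if (state == 0) {
      unsigned char t = tM[q];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
      state = (t == 0) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char t = tX[q];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i;
      state = (t == 1) ? 0 : 1;
    } else {
      unsigned char t = tY[q];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j;
      state = (t == 1) ? 0 : 2;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = score);
}
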