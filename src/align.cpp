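#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh), three modes:
//   0 = global, 1 = local, 2 = semiglobal (free end gaps; overhang columns
//       are not emitted, so the returned alignment covers only the aligned
//       spans of each input).
// Gap of length k costs gap_open + (k-1) * gap_extend (both <= 0).
// Deterministic tie-breaking: diagonal, then up (gap in b), then left
// (gap in a); within gap states the predecessor preference is M, same-gap
// extension, other-gap.

static const double NEG = -1e18;

enum State { SM = 0, SIX = 1, SIY = 2, START = 3 };

// anchor: 0 = none; 1 = local alignment must END within `slack` of b's end
// (best-scoring match-state cell in the last slack+1 columns).
// [[Rcpp::export]]
List align_cpp(std::string a, std::string b, double match, double mismatch,
               double gap_open, double gap_extend, int mode,
               int anchor = 0, int slack = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  if ((double)(n + 1) * (double)(m + 1) > 3.2e8)
    stop("alignment problem too large (> ~18k x 18k)");
  const size_t W = (size_t)m + 1, SZ = (size_t)(n + 1) * W;
  std::vector<float> M(SZ, (float)NEG), Ix(SZ, (float)NEG), Iy(SZ, (float)NEG);
  std::vector<signed char> tbM(SZ, START), tbIx(SZ, SM), tbIy(SZ, SM);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  M[at(0, 0)] = 0.0f;
  if (mode == 0) { // global boundaries live in the gap states
    for (int i = 1; i <= n; ++i) {
      Ix[at(i, 0)] = (float)(gap_open + (i - 1) * gap_extend);
      tbIx[at(i, 0)] = (i == 1) ? SM : SIX;
    }
    for (int j = 1; j <= m; ++j) {
      Iy[at(0, j)] = (float)(gap_open + (j - 1) * gap_extend);
      tbIy[at(0, j)] = (j == 1) ? SM : SIY;
    }
  } else { // local / semiglobal: alignments may start at any boundary point
    for (int i = 1; i <= n; ++i) M[at(i, 0)] = 0.0f;
    for (int j = 1; j <= m; ++j) M[at(0, j)] = 0.0f;
  }

  double best_local = 0.0; int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cb = b[j - 1];
      const double s = (ca == 'N' || cb == 'N') ? mismatch
                       : (ca == cb ? match : mismatch);
      // M: predecessor at (i-1, j-1), preference M, Ix, Iy
      {
        const size_t p = at(i - 1, j - 1);
        double pv = M[p]; int ps = SM;
        if (Ix[p] > pv) { pv = Ix[p]; ps = SIX; }
        if (Iy[p] > pv) { pv = Iy[p]; ps = SIY; }
        if (mode == 1 && pv < 0.0) { pv = 0.0; ps = START; }
        M[at(i, j)] = (float)(pv + s);
        tbM[at(i, j)] = (signed char)ps;
      }
      // Ix: gap in b (consume a char); predecessor at (i-1, j)
      {
        const size_t p = at(i - 1, j);
        double v = M[p] + gap_open; int ps = SM;
        if (Ix[p] + gap_extend > v) { v = Ix[p] + gap_extend; ps = SIX; }
        if (Iy[p] + gap_open > v) { v = Iy[p] + gap_open; ps = SIY; }
        Ix[at(i, j)] = (float)v;
        tbIx[at(i, j)] = (signed char)ps;
      }
      // Iy: gap in a (consume b char); predecessor at (i, j-1)
      {
        const size_t p = at(i, j - 1);
        double v = M[p] + gap_open; int ps = SM;
        if (Iy[p] + gap_extend > v) { v = Iy[p] + gap_extend; ps = SIY; }
        if (Ix[p] + gap_open > v) { v = Ix[p] + gap_open; ps = SIX; }
        Iy[at(i, j)] = (float)v;
        tbIy[at(i, j)] = (signed char)ps;
      }
      if (mode == 1 && M[at(i, j)] > best_local) {
        best_local = M[at(i, j)]; best_i = i; best_j = j;
      }
    }
  }

  // pick the traceback start
  int ei = n, ej = m, state = SM;
  double score;
  if (mode == 0) {
    const size_t p = at(n, m);
    score = M[p]; state = SM;
    if (Ix[p] > score) { score = Ix[p]; state = SIX; }
    if (Iy[p] > score) { score = Iy[p]; state = SIY; }
  } else if (mode == 1) {
    if (anchor == 1) { // re-select best cell among the anchored columns
      best_local = 0.0; best_i = 0; best_j = 0;
      const int jlo = std::max(1, m - slack);
      for (int ii = 1; ii <= n; ++ii)
        for (int jj = jlo; jj <= m; ++jj)
          if (M[at(ii, jj)] > best_local) {
            best_local = M[at(ii, jj)]; best_i = ii; best_j = jj;
          }
    }
    if (best_local <= 0.0) { // no positive-scoring cell: empty alignment
      return List::create(_["aligned_a"] = "", _["aligned_b"] = "",
                          _["score"] = 0.0,
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
    score = best_local; ei = best_i; ej = best_j; state = SM;
  } else { // semiglobal: best over last column then last row, states M,Ix,Iy
    score = NEG;
    for (int i = 0; i <= n; ++i) {
      const size_t p = at(i, m);
      const double cand[3] = { M[p], Ix[p], Iy[p] };
      for (int st = 0; st < 3; ++st)
        if (cand[st] > score) { score = cand[st]; ei = i; ej = m; state = st; }
    }
    for (int j = 0; j <= m; ++j) {
      const size_t p = at(n, j);
      const double cand[3] = { M[p], Ix[p], Iy[p] };
      for (int st = 0; st < 3; ++st)
        if (cand[st] > score) { score = cand[st]; ei = n; ej = j; state = st; }
    }
  }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = ei, j = ej;
  while (true) {
    if (state == SM) {
      if (i == 0 || j == 0) break; // boundary origin (global/semiglobal)
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const int prev = tbM[at(i, j)];
      --i; --j;
      if (prev == START) break; // local alignment start
      state = prev;
    } else if (state == SIX) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      const int prev = tbIx[at(i, j)];
      --i;
      state = prev;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const int prev = tbIy[at(i, j)];
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score,
                      _["a_start"] = i, _["a_end"] = ei,
                      _["b_start"] = j, _["b_end"] = ej);
}

// Exhaustive maximal tandem array scan. For every start s and unit length L
// in [min_unit, max_unit], anchor the unit at s and extend whole copies while
// each copy is within max_mm mismatches of the anchor copy; then count the
// exact-matching prefix of a trailing partial copy. Candidates need >= 2
// whole copies.
// [[Rcpp::export]]
DataFrame scan_tandem_cpp(std::string s, int min_unit, int max_unit,
                          int max_mm) {
  const int n = (int)s.size();
  std::vector<int> v_start, v_len, v_whole, v_partial, v_mm;
  for (int L = min_unit; L <= max_unit; ++L) {
    for (int st = 0; st + 2 * L <= n; ++st) {
      int whole = 1, mm_total = 0;
      int pos = st + L;
      while (pos + L <= n) {
        int mm = 0;
        for (int k = 0; k < L; ++k)
          if (s[pos + k] != s[st + k]) { ++mm; if (mm > max_mm) break; }
        if (mm > max_mm) break;
        mm_total += mm;
        ++whole;
        pos += L;
      }
      if (whole < 2) continue;
      int partial = 0;
      while (pos + partial < n && partial < L &&
             s[pos + partial] == s[st + partial])
        ++partial;
      v_start.push_back(st);
      v_len.push_back(L);
      v_whole.push_back(whole);
      v_partial.push_back(partial);
      v_mm.push_back(mm_total);
    }
  }
  return DataFrame::create(_["start"] = v_start, _["unit_len"] = v_len,
                           _["whole"] = v_whole, _["partial"] = v_partial,
                           _["mismatches"] = v_mm);
}
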