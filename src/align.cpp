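// Affine-gap global pairwise alignment with deterministic tie-breaking.
//
// Scoring: match/mismatch substitution scores; a gap of length L costs
// gap_open + L * gap_ext (the open penalty is charged once, the extension
// penalty for every gapped base including the first).
//
// Tie-breaking is fixed so identical inputs always yield the identical
// alignment: at the end cell and in the match state the preference order is
// M > X > Y; inside a gap state, extending the gap is preferred over
// opening; X consumes `a` (gap in `b`), Y consumes `b` (gap in `a`).
//
// fit = true turns the alignment into a "fit" of `a` inside `b`: leading and
// trailing gaps in `a` are free (used to locate a probe on a longer
// template window).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = -100000000;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext,
                  bool fit = false) {
  const int n = (int)a.size(), m = (int)b.size();
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<int> M((n + 1) * (m + 1), NEG);
  std::vector<int> X((n + 1) * (m + 1), NEG);  // gap in b (consume a)
  std::vector<int> Y((n + 1) * (m + 1), NEG);  // gap in a (consume b)

  M[idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -gap_open - i * gap_ext;
  for (int j = 1; j <= m; ++j)
    Y[idx(0, j)] = fit ? 0 : -gap_open - j * gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int best = M[idx(i - 1, j - 1)];
      if (X[idx(i - 1, j - 1)] > best) best = X[idx(i - 1, j - 1)];
      if (Y[idx(i - 1, j - 1)] > best) best = Y[idx(i - 1, j - 1)];
      if (best > NEG / 2) M[idx(i, j)] = best + s;

      int xbest = X[idx(i - 1, j)] - gap_ext;                  // extend
      int xo = M[idx(i - 1, j)] - gap_open - gap_ext;          // open from M
      if (xo > xbest) xbest = xo;
      int xy = Y[idx(i - 1, j)] - gap_open - gap_ext;          // switch
      if (xy > xbest) xbest = xy;
      if (xbest > NEG / 2) X[idx(i, j)] = xbest;

      int ybest = Y[idx(i, j - 1)] - gap_ext;
      int yo = M[idx(i, j - 1)] - gap_open - gap_ext;
      if (yo > ybest) ybest = yo;
      int yx = X[idx(i, j - 1)] - gap_open - gap_ext;
      if (yx > ybest) ybest = yx;
      if (ybest > NEG / 2) Y[idx(i, j)] = ybest;
    }
  }

  // End cell / end state
  int end_j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  int score;
  if (!fit) {
    score = M[idx(n, m)];
    state = 0;
    if (X[idx(n, m)] > score) { score = X[idx(n, m)]; state = 1; }
    if (Y[idx(n, m)] > score) { score = Y[idx(n, m)]; state = 2; }
  } else {
    score = NEG;
    state = 0;
    for (int j = 0; j <= m; ++j) {
      int sc = M[idx(n, j)], st = 0;
      if (X[idx(n, j)] > sc) { sc = X[idx(n, j)]; st = 1; }
      if (j > 0 && Y[idx(n, j)] > sc) { sc = Y[idx(n, j)]; st = 2; }
      if (sc > score) { score = sc; state = st; end_j = j; }
    }
  }

  std::string aa, bb;
  // trailing free gap in a (fit mode)
  for (int j = m; j > end_j; --j) { aa.push_back('-'); bb.push_back(b[j - 1]); }

  int i = n, j = end_j, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 || j == 0) break;
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      const int target = M[idx(i, j)] - s;
      int ni = i - 1, nj = j - 1;
      if (M[idx(ni, nj)] == target) st = 0;
      else if (X[idx(ni, nj)] == target) st = 1;
      else st = 2;
      i = ni; j = nj;
    } else if (st == 1) {
      if (i == 0) break;
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      const int v = X[idx(i, j)];
      if (i - 1 >= 0 && X[idx(i - 1, j)] - gap_ext == v) st = 1;
      else if (M[idx(i - 1, j)] - gap_open - gap_ext == v) st = 0;
      else st = 2;
      i = i - 1;
    } else {
      if (j == 0) break;
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      const int v = Y[idx(i, j)];
      if (fit && i == 0) {
        st = 2;  // free leading region; keep consuming b
      } else if (Y[idx(i, j - 1)] - gap_ext == v) st = 2;
      else if (M[idx(i, j - 1)] - gap_open - gap_ext == v) st = 0;
      else st = 1;
      j = j - 1;
    }
  }
  // leading remainder (only one of the two can be non-empty)
  while (i > 0) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; }
  while (j > 0) { aa.push_back('-'); bb.push_back(b[j - 1]); --j; }

  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = aa,
                      _["aligned_b"] = bb);
}
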