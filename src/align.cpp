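#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh affine-gap alignment over integer-coded sequences with an arbitrary
// (possibly asymmetric) substitution matrix S[ref_code, clone_code].
// A gap of length L costs gap_open + (L-1) * gap_ext (both <= 0).
// Traceback is deterministic: diagonal preferred over up (gap in clone)
// preferred over left (gap in ref), and the same ordering among predecessor
// states, so equal-score alignments always resolve the same way.

static const double NEG = -1e30;

// state codes
enum { ST_D = 0, ST_P = 1, ST_Q = 2, ST_START = 3 };

// [[Rcpp::export]]
List cpp_align_global(IntegerVector ref, IntegerVector clone,
                      NumericMatrix S, double gap_open, double gap_ext) {
  const int n = ref.size(), m = clone.size();
  const int W = m + 1;
  std::vector<double> D((n + 1) * W, NEG), P((n + 1) * W, NEG), Q((n + 1) * W, NEG);
  std::vector<unsigned char> tbD((n + 1) * W), tbP((n + 1) * W), tbQ((n + 1) * W);

  D[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    P[i * W] = gap_open + (i - 1) * gap_ext;
    tbP[i * W] = (i == 1) ? ST_D : ST_P;
  }
  for (int j = 1; j <= m; ++j) {
    Q[j] = gap_open + (j - 1) * gap_ext;
    tbQ[j] = (j == 1) ? ST_D : ST_Q;
  }

  for (int i = 1; i <= n; ++i) {
    const int ri = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = S(ri, clone[j - 1]);
      // D: align ref[i] to clone[j]
      double best = D[dg]; unsigned char tb = ST_D;
      if (P[dg] > best) { best = P[dg]; tb = ST_P; }
      if (Q[dg] > best) { best = Q[dg]; tb = ST_Q; }
      D[idx] = best + s; tbD[idx] = tb;
      // P: ref[i] against a gap (vertical / "up")
      best = D[up] + gap_open; tb = ST_D;
      if (P[up] + gap_ext > best) { best = P[up] + gap_ext; tb = ST_P; }
      if (Q[up] + gap_open > best) { best = Q[up] + gap_open; tb = ST_Q; }
      P[idx] = best; tbP[idx] = tb;
      // Q: clone[j] against a gap (horizontal / "left")
      best = D[lf] + gap_open; tb = ST_D;
      if (P[lf] + gap_open > best) { best = P[lf] + gap_open; tb = ST_P; }
      if (Q[lf] + gap_ext > best) { best = Q[lf] + gap_ext; tb = ST_Q; }
      Q[idx] = best; tbQ[idx] = tb;
    }
  }

  const int end = n * W + m;
  double score = D[end]; int state = ST_D;
  if (P[end] > score) { score = P[end]; state = ST_P; }
  if (Q[end] > score) { score = Q[end]; state = ST_Q; }

  // ops: 0 = diagonal, 1 = up (ref base vs gap), 2 = left (clone base vs gap)
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == ST_D) {
      ops.push_back('0'); state = tbD[idx]; --i; --j;
    } else if (state == ST_P) {
      ops.push_back('1'); state = tbP[idx]; --i;
    } else {
      ops.push_back('2'); state = tbQ[idx]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops);
}

// [[Rcpp::export]]
List cpp_align_local(IntegerVector ref, IntegerVector clone,
                     NumericMatrix S, double gap_open, double gap_ext) {
  const int n = ref.size(), m = clone.size();
  const int W = m + 1;
  std::vector<double> D((n + 1) * W, NEG), P((n + 1) * W, NEG), Q((n + 1) * W, NEG);
  std::vector<unsigned char> tbD((n + 1) * W), tbP((n + 1) * W), tbQ((n + 1) * W);

  for (int j = 0; j <= m; ++j) D[j] = 0.0;
  for (int i = 0; i <= n; ++i) D[i * W] = 0.0;

  double best_score = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ri = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = S(ri, clone[j - 1]);
      // empty-alignment restart preferred on ties (shortest alignment)
      double best = 0.0; unsigned char tb = ST_START;
      if (D[dg] > best) { best = D[dg]; tb = ST_D; }
      if (P[dg] > best) { best = P[dg]; tb = ST_P; }
      if (Q[dg] > best) { best = Q[dg]; tb = ST_Q; }
      double d = best + s;
      if (d < 0.0) { d = 0.0; tb = ST_START; }
      D[idx] = d; tbD[idx] = tb;

      best = D[up] + gap_open; tb = ST_D;
      if (P[up] + gap_ext > best) { best = P[up] + gap_ext; tb = ST_P; }
      if (Q[up] + gap_open > best) { best = Q[up] + gap_open; tb = ST_Q; }
      P[idx] = best; tbP[idx] = tb;

      best = D[lf] + gap_open; tb = ST_D;
      if (P[lf] + gap_open > best) { best = P[lf] + gap_open; tb = ST_P; }
      if (Q[lf] + gap_ext > best) { best = Q[lf] + gap_ext; tb = ST_Q; }
      Q[idx] = best; tbQ[idx] = tb;

      if (D[idx] > best_score) { best_score = D[idx]; bi = i; bj = j; }
    }
  }

  std::string ops;
  int i = bi, j = bj, state = ST_D;
  if (best_score > 0.0) {
    while (true) {
      const int idx = i * W + j;
      if (state == ST_D) {
        if (tbD[idx] == ST_START && D[idx] == 0.0) break; // floored cell, not part
        ops.push_back('0');
        const int nxt = tbD[idx];
        --i; --j;
        if (nxt == ST_START) break;
        state = nxt;
      } else if (state == ST_P) {
        ops.push_back('1'); state = tbP[idx]; --i;
      } else {
        ops.push_back('2'); state = tbQ[idx]; --j;
      }
    }
    std::reverse(ops.begin(), ops.end());
  }
  return List::create(_["score"] = best_score, _["ops"] = ops,
                      _["ref_start"] = i + 1, _["ref_end"] = bi,
                      _["clone_start"] = j + 1, _["clone_end"] = bj);
}
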