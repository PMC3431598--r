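#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) between an encoded query and subject
// window, with X-drop style trimming of the traceback tails: each end of
// the optimal local path is cut back to its last score peak once the
// running score has dropped more than `xdrop` below that peak. This is
// what keeps weakly positive read-through across exon/intron boundaries
// out of the reported HSP.
//
// q, s: 0-based integer encodings of the sequences (indices into S).
// S: substitution matrix. Returns 1-based trimmed coordinates.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, NumericMatrix S,
              double gap_open, double gap_ext, double xdrop) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) return List::create(Named("score") = 0.0);
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), 0.0),
      F((n + 1) * (m + 1), 0.0);
  // traceback: 0 stop, 1 diag, 2 up(F, gap in subject), 3 left(E, gap in query)
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * (m + 1) + j;
      const double eo = H[id - 1] - gap_open, ee = E[id - 1] - gap_ext;
      E[id] = eo >= ee ? eo : ee;
      tbE[id] = eo >= ee ? 0 : 1;
      const double fo = H[id - (m + 1)] - gap_open,
                   fe = F[id - (m + 1)] - gap_ext;
      F[id] = fo >= fe ? fo : fe;
      tbF[id] = fo >= fe ? 0 : 1;
      const double diag =
          H[id - (m + 1) - 1] + S(q[i - 1], s[j - 1]);
      double h = 0.0;
      unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (F[id] > h) { h = F[id]; tb = 2; }
      if (E[id] > h) { h = E[id]; tb = 3; }
      H[id] = h;
      tbH[id] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return List::create(Named("score") = 0.0);

  // traceback, collecting per-column scores (path stored reversed)
  std::vector<double> col;
  std::vector<int> qpos, spos;  // 0 when gapped
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int id = i * (m + 1) + j;
    if (state == 0) {
      const unsigned char tb = tbH[id];
      if (tb == 0) break;
      if (tb == 1) {
        col.push_back(S(q[i - 1], s[j - 1]));
        qpos.push_back(i); spos.push_back(j);
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      col.push_back(tbF[id] == 0 ? -gap_open : -gap_ext);
      qpos.push_back(i); spos.push_back(0);
      state = tbF[id] == 0 ? 0 : 2;
      --i;
    } else {
      col.push_back(tbE[id] == 0 ? -gap_open : -gap_ext);
      qpos.push_back(0); spos.push_back(j);
      state = tbE[id] == 0 ? 0 : 3;
      --j;
    }
  }
  const int len = col.size();
  if (len == 0) return List::create(Named("score") = 0.0);
  // forward order
  std::reverse(col.begin(), col.end());
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(spos.begin(), spos.end());

  // X-drop segmentation: split the column-score profile wherever the
  // running score falls more than xdrop below its last peak (an
  // extension would have stopped there), keep the best-scoring segment,
  // then trim its left edge with the same rule. This prevents weak
  // read-through between two strong blocks from welding junk onto an
  // HSP, while still anchoring on the strongest block.
  double acc = 0.0, peak_val = -1e18;
  int seg_start = 0, peak_idx = 0;
  double best_seg = -1e18;
  int right = len - 1, left0 = 0;
  for (int k = 0; k < len; ++k) {
    acc += col[k];
    if (acc > peak_val) { peak_val = acc; peak_idx = k; }
    if (acc < peak_val - xdrop) {
      if (peak_val > best_seg) {
        best_seg = peak_val; right = peak_idx; left0 = seg_start;
      }
      seg_start = k + 1; acc = 0.0; peak_val = -1e18; peak_idx = k + 1;
    }
  }
  if (peak_val > best_seg) { best_seg = peak_val; right = peak_idx; left0 = seg_start; }
  if (right < left0) return List::create(Named("score") = 0.0);
  acc = 0.0; peak_val = -1e18;
  int left = left0, peak_l = right;
  for (int k = right; k >= left0; --k) {
    acc += col[k];
    if (acc > peak_val) { peak_val = acc; peak_l = k; }
    if (acc < peak_val - xdrop) { left = peak_l; break; }
  }
  if (left > right) return List::create(Named("score") = 0.0);

  double score = 0.0;
  int qs = 0, qe = 0, ss = 0, se = 0;
  for (int k = left; k <= right; ++k) {
    score += col[k];
    if (qpos[k] > 0) { if (qs == 0) qs = qpos[k]; qe = qpos[k]; }
    if (spos[k] > 0) { if (ss == 0) ss = spos[k]; se = spos[k]; }
  }
  if (qs == 0 || ss == 0 || score <= 0.0)
    return List::create(Named("score") = 0.0);
  return List::create(Named("score") = score, Named("q_start") = qs,
                      Named("q_end") = qe, Named("s_start") = ss,
                      Named("s_end") = se);
}
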