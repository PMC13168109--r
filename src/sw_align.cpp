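// Affine-gap Smith-Waterman local alignment with traceback, returning the
// statistics needed for identity/coverage-threshold clustering:
// matches, alignment columns (gap columns included), aligned spans.
// Gap cost convention matches BLAST/Biostrings: a gap of length L costs
// gap_open + L * gap_ext.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List sw_align_stats(IntegerVector p, IntegerVector q, IntegerMatrix score,
                    double gap_open, double gap_ext) {
  const int m = p.size(), n = q.size();
  const double NEG = -1e18;
  // score matrices (full, for traceback)
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG);
  std::vector<double> F((m + 1) * (n + 1), NEG);
  // traceback codes: tbH 0=stop,1=diag,2=fromE,3=fromF; tbE/tbF 0=open,1=extend
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int ij = at(i, j);
      // E: gap in p (consumes q[j])
      double e_open = H[at(i, j - 1)] - gap_open - gap_ext;
      double e_ext = E[at(i, j - 1)] - gap_ext;
      if (e_ext > e_open) { E[ij] = e_ext; tbE[ij] = 1; }
      else { E[ij] = e_open; tbE[ij] = 0; }
      // F: gap in q (consumes p[i])
      double f_open = H[at(i - 1, j)] - gap_open - gap_ext;
      double f_ext = F[at(i - 1, j)] - gap_ext;
      if (f_ext > f_open) { F[ij] = f_ext; tbF[ij] = 1; }
      else { F[ij] = f_open; tbF[ij] = 0; }
      // H: best of stop / diagonal / E / F
      double diag = H[at(i - 1, j - 1)] +
        score(p[i - 1], q[j - 1]);
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[ij] > h) { h = E[ij]; tb = 2; }
      if (F[ij] > h) { h = F[ij]; tb = 3; }
      H[ij] = h; tbH[ij] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, columns = 0;
  int p_end = bi, q_end = bj, p_start = bi + 1, q_start = bj + 1;
  // traceback from the best cell
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int ij = at(i, j);
    if (state == 0) {
      unsigned char tb = tbH[ij];
      if (tb == 0) break;
      if (tb == 1) {
        ++columns;
        if (p[i - 1] == q[j - 1]) ++matches;
        p_start = i; q_start = j;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // in E: gap in p, consume q[j]
      ++columns;
      q_start = j;
      if (tbE[ij] == 0) state = 0;
      --j;
    } else { // in F: gap in q, consume p[i]
      ++columns;
      p_start = i;
      if (tbF[ij] == 0) state = 0;
      --i;
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["columns"] = 0, _["p_start"] = 0, _["p_end"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0);
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["p_start"] = p_start, _["p_end"] = p_end,
                      _["q_start"] = q_start, _["q_end"] = q_end);
}
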