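#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-pixel windowed GLCM texture features.
//
// For every pixel whose (win x win) window lies fully inside the image, the
// gray-level co-occurrence matrix of the window at offset (dx, dy) is built
// symmetrically (each pair counted in both directions), normalized to
// probabilities, and summarized by eight Haralick-style statistics:
// mean, variance, homogeneity, contrast, dissimilarity ("heterogeneity"),
// entropy (natural log), angular second moment, and correlation
// (0 when the marginal variance is 0). Rows of the returned matrix are
// valid pixels in column-major image order.
//
// q: integer matrix of quantized levels in [0, levels).
// [[Rcpp::export]]
NumericMatrix glcm_window_stats(IntegerMatrix q, int levels, int win,
                                int dx, int dy) {
  int nr = q.nrow(), nc = q.ncol();
  int ni = win - std::abs(dy), nj = win - std::abs(dx); // pair grid in window
  int npair = ni * nj;
  if (npair <= 0) stop("offset larger than window");
  int nvalid_r = nr - win + 1, nvalid_c = nc - win + 1;
  if (nvalid_r <= 0 || nvalid_c <= 0)
    return NumericMatrix(0, 8);
  NumericMatrix out(nvalid_r * nvalid_c, 8);

  std::vector<int> code(2 * npair), cnt(2 * npair);
  int row = 0;
  for (int cc = 0; cc < nvalid_c; ++cc) {
    for (int rr = 0; rr < nvalid_r; ++rr, ++row) {
      // collect symmetric ordered pairs (a,b) and (b,a)
      int m = 0;
      for (int j = 0; j < nj; ++j) {
        for (int i = 0; i < ni; ++i) {
          int r0 = rr + (dy >= 0 ? i : i - dy);
          int c0 = cc + (dx >= 0 ? j : j - dx);
          int a = q(r0, c0), b = q(r0 + dy, c0 + dx);
          code[m++] = a * levels + b;
          code[m++] = b * levels + a;
        }
      }
      int total = m;
      // quadratic dedupe over a tiny list (at most 2*npair codes)
      int ncell = 0;
      for (int k = 0; k < m; ++k) {
        bool found = false;
        for (int u = 0; u < ncell; ++u) {
          if (code[u] == code[k]) { cnt[u]++; found = true; break; }
        }
        if (!found) { code[ncell] = code[k]; cnt[ncell] = 1; ncell++; }
      }
      double mean = 0, var = 0, hom = 0, con = 0, dis = 0, ent = 0,
             asm_ = 0, corr_num = 0;
      for (int u = 0; u < ncell; ++u) {
        double p = (double)cnt[u] / total;
        int i = code[u] / levels, j = code[u] % levels;
        mean += p * i;
        hom += p / (1.0 + (i - j) * (i - j));
        con += p * (i - j) * (i - j);
        dis += p * std::abs(i - j);
        ent -= p * std::log(p);
        asm_ += p * p;
      }
      for (int u = 0; u < ncell; ++u) {
        double p = (double)cnt[u] / total;
        int i = code[u] / levels, j = code[u] % levels;
        var += p * (i - mean) * (i - mean);
        corr_num += p * (i - mean) * (j - mean);
      }
      double corr = (var > 0) ? corr_num / var : 0.0;
      out(row, 0) = mean;  out(row, 1) = var;  out(row, 2) = hom;
      out(row, 3) = con;   out(row, 4) = dis;  out(row, 5) = ent;
      out(row, 6) = asm_;  out(row, 7) = corr;
    }
  }
  return out;
}
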