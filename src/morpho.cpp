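#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rasterize a tube of circular cross-section around a planar midline curve.
// curve: (n x 2) matrix of (row, col) pixel coordinates ordered by arc
// length (possibly adaptively subsampled); r_px: local radius in pixels;
// s: normalized arc position; pad: per-sample stamp padding covering the
// local sample spacing.  Each pixel is assigned to its nearest curve sample
// and is foreground when its distance is at most the local radius.  The
// tube is cut flat at both curve ends: pixels assigned to samples near an
// end (s < clip0 or s > 1 - clip1) must lie on the body side of the end
// plane, so the rendered solid matches the solid of revolution along the
// curve, without spherical end caps.  An optional darker lumen band of
// given half-width is drawn for samples with s in [lumen_s0, lumen_s1].
// [[Rcpp::export]]
List render_tube_cpp(NumericMatrix curve, NumericVector r_px, NumericVector s,
                     NumericVector pad, int nrow, int ncol,
                     double fg, double bg, double clip0, double clip1,
                     bool has_lumen, NumericVector lumen_halfwidth_px,
                     double lumen_intensity, double lumen_s0, double lumen_s1) {
  const int n = curve.nrow();
  std::vector<double> mindist2(static_cast<size_t>(nrow) * ncol, -1.0);
  std::vector<int> argmin(static_cast<size_t>(nrow) * ncol, -1);

  for (int k = 0; k < n; ++k) {
    const double cr = curve(k, 0), cc = curve(k, 1);
    const double w = r_px[k] + pad[k];
    const int r0 = std::max(0, (int)std::floor(cr - w));
    const int r1 = std::min(nrow - 1, (int)std::ceil(cr + w));
    const int c0 = std::max(0, (int)std::floor(cc - w));
    const int c1 = std::min(ncol - 1, (int)std::ceil(cc + w));
    for (int i = r0; i <= r1; ++i) {
      const double di = i - cr;
      for (int j = c0; j <= c1; ++j) {
        const double dj = j - cc;
        const double d2 = di * di + dj * dj;
        const size_t idx = (size_t)i + (size_t)j * nrow;
        if (mindist2[idx] < 0.0 || d2 < mindist2[idx]) {
          mindist2[idx] = d2;
          argmin[idx] = k;
        }
      }
    }
  }

  // inward unit tangents at the two curve ends, for the flat end cut
  double t0r = curve(1, 0) - curve(0, 0), t0c = curve(1, 1) - curve(0, 1);
  double nrm = std::sqrt(t0r * t0r + t0c * t0c);
  t0r /= nrm; t0c /= nrm;
  double t1r = curve(n - 2, 0) - curve(n - 1, 0),
         t1c = curve(n - 2, 1) - curve(n - 1, 1);
  nrm = std::sqrt(t1r * t1r + t1c * t1c);
  t1r /= nrm; t1c /= nrm;

  NumericMatrix pixels(nrow, ncol);
  LogicalMatrix mask(nrow, ncol);
  std::fill(pixels.begin(), pixels.end(), bg);
  for (int j = 0; j < ncol; ++j) {
    for (int i = 0; i < nrow; ++i) {
      const size_t idx = (size_t)i + (size_t)j * nrow;
      const int k = argmin[idx];
      if (k < 0) continue;
      const double d = std::sqrt(mindist2[idx]);
      if (d > r_px[k]) continue;
      if (s[k] < clip0 &&
          (i - curve(0, 0)) * t0r + (j - curve(0, 1)) * t0c < 0)
        continue;
      if (s[k] > 1.0 - clip1 &&
          (i - curve(n - 1, 0)) * t1r + (j - curve(n - 1, 1)) * t1c < 0)
        continue;
      mask(i, j) = true;
      double v = fg;
      if (has_lumen && s[k] >= lumen_s0 && s[k] <= lumen_s1 &&
          d <= lumen_halfwidth_px[k])
        v = lumen_intensity;
      pixels(i, j) = v;
    }
  }
  return List::create(_["pixels"] = pixels, _["mask"] = mask);
}

// Zhang-Suen two-subiteration thinning of a binary mask down to its
// one-pixel-wide 8-connected skeleton.  Queue-based: only pixels whose
// neighborhood changed since they were last examined are re-tested, so the
// cost is proportional to the number of removed pixels, not to
// iterations x image area.  The mask must not touch the image border.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  const int nrow = mask.nrow(), ncol = mask.ncol();
  const size_t N = (size_t)nrow * ncol;
  std::vector<unsigned char> m(N, 0);
  std::vector<int> cand;
  cand.reserve(1024);
  for (int j = 1; j < ncol - 1; ++j)
    for (int i = 1; i < nrow - 1; ++i)
      if (mask(i, j)) m[(size_t)i + (size_t)j * nrow] = 1;

  // initial candidates: foreground pixels with at least one background
  // 8-neighbor (interior pixels cannot be removed)
  std::vector<unsigned char> queued(N, 0);
  const int off[8] = {-1, 1, -nrow, nrow,
                      -1 - nrow, 1 - nrow, -1 + nrow, 1 + nrow};
  for (int j = 1; j < ncol - 1; ++j)
    for (int i = 1; i < nrow - 1; ++i) {
      const size_t idx = (size_t)i + (size_t)j * nrow;
      if (!m[idx]) continue;
      for (int t = 0; t < 8; ++t)
        if (!m[idx + off[t]]) {
          cand.push_back((int)idx);
          queued[idx] = 1;
          break;
        }
    }

  std::vector<int> kill, next;
  while (!cand.empty()) {
    bool removed_any = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (size_t c = 0; c < cand.size(); ++c) {
        const size_t idx = (size_t)cand[c];
        if (!m[idx]) continue;
        const int p2 = m[idx - 1], p6 = m[idx + 1];
        const int p8 = m[idx - nrow], p4 = m[idx + nrow];
        const int p9 = m[idx - 1 - nrow], p3 = m[idx - 1 + nrow];
        const int p7 = m[idx + 1 - nrow], p5 = m[idx + 1 + nrow];
        const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (B < 2 || B > 6) continue;
        int A = 0;
        const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
        for (int t = 0; t < 8; ++t)
          if (seq[t] == 0 && seq[t + 1] == 1) ++A;
        if (A != 1) continue;
        if (step == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        kill.push_back((int)idx);
      }
      for (size_t t = 0; t < kill.size(); ++t) m[(size_t)kill[t]] = 0;
      if (!kill.empty()) removed_any = true;
      // neighbors of removed pixels become candidates for the next round
      for (size_t t = 0; t < kill.size(); ++t) {
        const size_t idx = (size_t)kill[t];
        for (int o = 0; o < 8; ++o) {
          const size_t nb = idx + off[o];
          if (m[nb] && queued[nb] != 2) {
            next.push_back((int)nb);
            queued[nb] = 2;  // mark for the next round
          }
        }
      }
    }
    if (!removed_any) break;
    // survivors of this round keep their queued flag only if re-marked
    for (size_t c = 0; c < cand.size(); ++c)
      if (queued[(size_t)cand[c]] == 1) queued[(size_t)cand[c]] = 0;
    for (size_t c = 0; c < next.size(); ++c) queued[(size_t)next[c]] = 1;
    cand.swap(next);
    next.clear();
  }

  LogicalMatrix out(nrow, ncol);
  for (size_t idx = 0; idx < N; ++idx)
    if (m[idx]) out[idx] = true;
  return out;
}
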