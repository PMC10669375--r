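#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labelling of a logical array (6 or 26 neighbours),
// iterative flood fill.  Labels are 1..n in discovery order; 0 = background.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur / ((R_xlen_t)nx * ny);
      int rem = cur - (R_xlen_t)z * nx * ny;
      int y = rem / nx, x = rem - y * nx;
      for (size_t k = 0; k < ox.size(); ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Gaussian-weighted local smoothed-histogram mode for one CT section.
//
// For every node (node_r[i], node_c[j]) (1-based) with center_ok true, the
// radiodensities of included pixels inside the circular window (offsets
// off_r/off_c with Gaussian weights off_w) are accumulated into a weighted
// 1-HU-bin histogram over [lo, hi] (bins anchored at lo, so a global HU
// offset that shifts lo equally leaves bin contents unchanged).  The
// histogram is smoothed with a 1-D Gaussian of sd smooth_sd and the centre
// of the maximal bin is returned; ties break to the lower HU.  Nodes whose
// in-range weight is below min_frac of the full window weight are
// unavailable (NA).
// [[Rcpp::export(rng = false)]]
List cpp_local_mode_slice(NumericMatrix img, LogicalMatrix include,
                          LogicalMatrix center_ok,
                          IntegerVector node_r, IntegerVector node_c,
                          IntegerVector off_r, IntegerVector off_c,
                          NumericVector off_w, double total_w,
                          double lo, double hi,
                          double smooth_sd, double min_frac) {
  const int nr = node_r.size(), nc = node_c.size();
  const int rows = img.nrow(), cols = img.ncol();
  NumericMatrix value(nr, nc);
  LogicalMatrix avail(nr, nc);
  std::fill(value.begin(), value.end(), NA_REAL);
  std::fill(avail.begin(), avail.end(), FALSE);
  const int nbins = (int)std::ceil(hi - lo);
  if (nbins < 1) return List::create(_["value"] = value, _["available"] = avail);

  const int K = std::max(1, (int)std::ceil(3.0 * smooth_sd));
  std::vector<double> kern(2 * K + 1);
  for (int k = -K; k <= K; ++k)
    kern[k + K] = std::exp(-0.5 * (double)k * k / (smooth_sd * smooth_sd));

  std::vector<double> hist(nbins), sm(nbins);
  const int noff = off_r.size();
  for (int i = 0; i < nr; ++i) {
    const int r0 = node_r[i] - 1;
    for (int j = 0; j < nc; ++j) {
      const int c0 = node_c[j] - 1;
      if (!center_ok(r0, c0)) continue;
      std::fill(hist.begin(), hist.end(), 0.0);
      double wsum = 0.0;
      for (int k = 0; k < noff; ++k) {
        const int r = r0 + off_r[k], c = c0 + off_c[k];
        if (r < 0 || r >= rows || c < 0 || c >= cols) continue;
        if (!include(r, c)) continue;
        const double v = img(r, c);
        if (v < lo || v > hi) continue;
        int b = (int)std::floor(v - lo);
        if (b >= nbins) b = nbins - 1;
        hist[b] += off_w[k];
        wsum += off_w[k];
      }
      if (wsum < min_frac * total_w) continue;
      int best = -1;
      double bestval = -1.0;
      for (int b = 0; b < nbins; ++b) {
        double g = 0.0;
        const int k0 = std::max(0, b - K), k1 = std::min(nbins - 1, b + K);
        for (int k = k0; k <= k1; ++k) g += hist[k] * kern[k - b + K];
        sm[b] = g;
        if (g > bestval) { bestval = g; best = b; }
      }
      if (best < 0 || bestval <= 0.0) continue;
      value(i, j) = lo + best + 0.5;
      avail(i, j) = TRUE;
    }
  }
  return List::create(_["value"] = value, _["available"] = avail);
}
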