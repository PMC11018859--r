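#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at (r, c), 0-based continuous pixel-center coords.
// Returns fill when the sample point falls outside the image.
static inline double sampleBilinear(const NumericMatrix& img, double r, double c,
                                    double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return fill;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == nr - 1) r0--;
  if (c0 == nc - 1) c0--;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  const double fr = r - r0, fc = c - c0;
  const double v00 = img(r0, c0), v01 = img(r0, c0 + 1);
  const double v10 = img(r0 + 1, c0), v11 = img(r0 + 1, c0 + 1);
  return v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
         v10 * fr * (1 - fc) + v11 * fr * fc;
}

// Warp img into an output grid of the same shape. m = (a11,a12,a13,a21,a22,a23)
// maps output (row, col) [0-based] to source coords:
//   src_r = a11*row + a12*col + a13 ; src_c = a21*row + a22*col + a23
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericVector m, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double a11 = m[0], a12 = m[1], a13 = m[2];
  const double a21 = m[3], a22 = m[4], a23 = m[5];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      out(r, c) = sampleBilinear(img, a11 * r + a12 * c + a13,
                                 a21 * r + a22 * c + a23, fill);
    }
  }
  return out;
}

// Mean squared difference between ref and mov warped through m, evaluated on a
// strided subgrid; only sample points landing inside mov contribute.
// [[Rcpp::export]]
List cpp_warp_ssd(NumericMatrix ref, NumericMatrix mov, NumericVector m,
                  int stride) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const double a11 = m[0], a12 = m[1], a13 = m[2];
  const double a21 = m[3], a22 = m[4], a23 = m[5];
  const int mnr = mov.nrow(), mnc = mov.ncol();
  double acc = 0.0;
  long n = 0;
  for (int c = 0; c < nc; c += stride) {
    for (int r = 0; r < nr; r += stride) {
      const double sr = a11 * r + a12 * c + a13;
      const double sc = a21 * r + a22 * c + a23;
      if (sr < 0.0 || sc < 0.0 || sr > mnr - 1.0 || sc > mnc - 1.0) continue;
      const double d = ref(r, c) - sampleBilinear(mov, sr, sc, 0.0);
      acc += d * d;
      ++n;
    }
  }
  return List::create(_["mse"] = (n > 0) ? acc / n : NA_REAL, _["n"] = (double)n);
}

// For every background pixel within `radius` (pixels, Euclidean, pixel-center
// metric) of a labeled pixel, report the label of the nearest labeled pixel
// and the squared distance to it. Ties go to the smallest label. Exhaustive
// window scan: exact for any radius, intended for small expansion radii.
// [[Rcpp::export]]
List cpp_nearest_label(IntegerMatrix labels, double radius) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const int w = (int)std::ceil(radius);
  const double r2max = radius * radius;
  IntegerMatrix nearest(nr, nc);
  NumericMatrix dist2(nr, nc);
  std::fill(dist2.begin(), dist2.end(), R_PosInf);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) != 0) {
        nearest(r, c) = labels(r, c);
        dist2(r, c) = 0.0;
        continue;
      }
      double best = R_PosInf;
      int bestLab = 0;
      const int r0 = std::max(0, r - w), r1 = std::min(nr - 1, r + w);
      const int c0 = std::max(0, c - w), c1 = std::min(nc - 1, c + w);
      for (int cc = c0; cc <= c1; ++cc) {
        const double dc = (double)(cc - c);
        for (int rr = r0; rr <= r1; ++rr) {
          const int lab = labels(rr, cc);
          if (lab == 0) continue;
          const double dr = (double)(rr - r);
          const double d2 = dr * dr + dc * dc;
          if (d2 > r2max) continue;
          if (d2 < best || (d2 == best && lab < bestLab)) {
            best = d2;
            bestLab = lab;
          }
        }
      }
      nearest(r, c) = bestLab;
      dist2(r, c) = best;
    }
  }
  return List::create(_["label"] = nearest, _["dist2"] = dist2);
}
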