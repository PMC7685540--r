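#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation of a rigid template against an image over a
// list of candidate poses.
//
// image    : H x W matrix, pixel (row y, col x) at 1-based integer centres
// off_x/y  : template sample offsets relative to the template centroid (px)
// tvals    : template intensities at those offsets
// cx, cy   : template centroid in image coordinates at the reference pose
// tx,ty,rot: candidate pose parameters (same length); the template offsets
//            are rotated by rot (degrees, +x towards +y) and translated by
//            (tx, ty) from the reference centroid
//
// Returns NCC in [-1, 1] per pose; 0 when the image patch has (near) zero
// variance; NA when any sample falls outside the image.
// [[Rcpp::export]]
NumericVector ncc_pose_scores(const NumericMatrix& image,
                              const NumericVector& off_x,
                              const NumericVector& off_y,
                              const NumericVector& tvals,
                              double cx, double cy,
                              const NumericVector& tx,
                              const NumericVector& ty,
                              const NumericVector& rot_deg) {
  const int npx = tvals.size();
  const int np = tx.size();
  const int H = image.nrow(), W = image.ncol();
  // raw pointers: the bilinear gather dominates the tracking runtime
  const double *im = &image[0];
  const double *ox = &off_x[0], *oy = &off_y[0], *tv = &tvals[0];

  double tmean = 0.0;
  for (int i = 0; i < npx; ++i) tmean += tv[i];
  tmean /= npx;
  double tss = 0.0;
  for (int i = 0; i < npx; ++i) {
    const double d = tv[i] - tmean;
    tss += d * d;
  }

  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double th = rot_deg[p] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    const double px = cx + tx[p], py = cy + ty[p];
    double sb = 0.0, sbb = 0.0, sab = 0.0;
    bool ok = true;
    for (int i = 0; i < npx; ++i) {
      const double x = px + c * ox[i] - s * oy[i];
      const double y = py + s * ox[i] + c * oy[i];
      // truncation equals floor for the in-range (positive) case; any
      // negative coordinate fails the bounds check below anyway
      const int x0 = (int)x, y0 = (int)y;
      if (x0 < 1 || x0 + 1 > W || y0 < 1 || y0 + 1 > H) { ok = false; break; }
      const double fx = x - x0, fy = y - y0;
      // column-major; pixel (x0, y0) lives at linear index (x0-1)*H + y0-1
      const double *col0 = im + (size_t)(x0 - 1) * H;
      const double *col1 = col0 + H;
      const double v00 = col0[y0 - 1], v01 = col1[y0 - 1];
      const double v10 = col0[y0], v11 = col1[y0];
      const double b = v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
                       v10 * (1 - fx) * fy + v11 * fx * fy;
      sb += b;
      sbb += b * b;
      sab += tv[i] * b;
    }
    if (!ok) { out[p] = NA_REAL; continue; }
    const double bss = sbb - sb * sb / npx;
    const double cov = sab - sb * tmean;
    if (tss <= 1e-12 || bss <= 1e-12) { out[p] = 0.0; continue; }
    out[p] = cov / std::sqrt(tss * bss);
  }
  return out;
}
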