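#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize agent centres into an npix x npix x nchan count image at
// 1 um / pixel. Pixel (1,1) maps to the domain corner (-L/2, -L/2);
// each agent is drawn as a filled disc of the given diameter around its
// (continuous) centre, so discs land at sub-pixel accuracy.
// [[Rcpp::export]]
IntegerVector cpp_rasterize(NumericVector px, NumericVector py,
                            IntegerVector channel, int npix, int nchan,
                            double diameter) {
  double half = (npix - 1) / 2.0;
  double rad = diameter / 2.0;
  double r2 = rad * rad;
  IntegerVector img((R_xlen_t) npix * npix * nchan);
  int n = px.size();
  for (int a = 0; a < n; ++a) {
    int ch = channel[a];
    if (ch < 0 || ch >= nchan) stop("channel index out of range");
    double cx = px[a] + half, cy = py[a] + half;
    int ilo = std::max(0, (int) std::ceil(cx - rad));
    int ihi = std::min(npix - 1, (int) std::floor(cx + rad));
    int jlo = std::max(0, (int) std::ceil(cy - rad));
    int jhi = std::min(npix - 1, (int) std::floor(cy + rad));
    for (int j = jlo; j <= jhi; ++j) {
      double dy = j - cy;
      for (int i = ilo; i <= ihi; ++i) {
        double dx = i - cx;
        if (dx * dx + dy * dy <= r2)
          img[i + (R_xlen_t) npix * (j + (R_xlen_t) npix * ch)] += 1;
      }
    }
  }
  img.attr("dim") = IntegerVector::create(npix, npix, nchan);
  return img;
}

// Median radius, across nrays evenly spaced rays from (cx, cy), of the
// outermost (and innermost) foreground crossing of a logical mask.
// Returns a matrix with one row per ray: outermost, innermost (-1 if the
// ray never crosses foreground).
// [[Rcpp::export]]
NumericMatrix cpp_ray_crossings(LogicalVector mask, int npix,
                                double cx, double cy, int nrays) {
  NumericMatrix out(nrays, 2);
  double rmax = npix * 0.75;  // beyond the half-diagonal of interest
  for (int k = 0; k < nrays; ++k) {
    double th = 2.0 * M_PI * k / nrays;
    double dx = std::cos(th), dy = std::sin(th);
    double outer = -1.0, inner = -1.0;
    for (double r = 0.0; r <= rmax; r += 1.0) {
      int i = (int) std::floor(cx + r * dx + 0.5);
      int j = (int) std::floor(cy + r * dy + 0.5);
      if (i < 0 || j < 0 || i >= npix || j >= npix) break;
      if (mask[i + (R_xlen_t) npix * j]) {
        outer = r;
        if (inner < 0) inner = r;
      }
    }
    out(k, 0) = outer;
    out(k, 1) = inner;
  }
  return out;
}
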