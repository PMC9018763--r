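// 3D convolution, stride 1, zero padding (k-1)/2, k in {1,3}.
// Direct accumulation; at the narrow channel widths this engine uses
// (4-16 channels) the straightforward loops outperform im2col+GEMM.
//
// Layouts (column-major, matching R):
//   feature maps (C, D, H, W): index c + C*(z + D*(y + H*x))
//   weights (Cout, Cin, k, k, k)

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int cin, int cout, int D, int H, int W, int k) {
  const int pad = (k - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(cout) * D * H * W);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* bp = b.begin();
  double* op = out.begin();
  std::vector<double> acc(cout);
  for (int ox = 0; ox < W; ++ox)
    for (int oy = 0; oy < H; ++oy)
      for (int oz = 0; oz < D; ++oz) {
        for (int c = 0; c < cout; ++c) acc[c] = bp[c];
        for (int tx = 0; tx < k; ++tx) {
          int ix = ox + tx - pad; if (ix < 0 || ix >= W) continue;
          for (int ty = 0; ty < k; ++ty) {
            int iy = oy + ty - pad; if (iy < 0 || iy >= H) continue;
            for (int tz = 0; tz < k; ++tz) {
              int iz = oz + tz - pad; if (iz < 0 || iz >= D) continue;
              const double* xv = xp + (size_t)cin * (iz + (size_t)D * (iy + (size_t)H * ix));
              const double* wt = wp + (size_t)cout * cin * (tz + (size_t)k * (ty + (size_t)k * tx));
              for (int ci = 0; ci < cin; ++ci) {
                const double xvci = xv[ci];
                const double* wcol = wt + (size_t)cout * ci;
                for (int c = 0; c < cout; ++c) acc[c] += wcol[c] * xvci;
              }
            }
          }
        }
        double* ov = op + (size_t)cout * (oz + (size_t)D * (oy + (size_t)H * ox));
        for (int c = 0; c < cout; ++c) ov[c] = acc[c];
      }
  out.attr("dim") = IntegerVector::create(cout, D, H, W);
  return out;
}

// Backward pass: returns list(gx, gw, gb).
// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
               int cin, int cout, int D, int H, int W, int k) {
  const int pad = (k - 1) / 2;
  NumericVector gx(static_cast<R_xlen_t>(cin) * D * H * W);
  NumericVector gw(static_cast<R_xlen_t>(cout) * cin * k * k * k);
  NumericVector gb(cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  double* gbp = gb.begin();
  for (int ox = 0; ox < W; ++ox)
    for (int oy = 0; oy < H; ++oy)
      for (int oz = 0; oz < D; ++oz) {
        const double* gv = gp + (size_t)cout * (oz + (size_t)D * (oy + (size_t)H * ox));
        for (int c = 0; c < cout; ++c) gbp[c] += gv[c];
        for (int tx = 0; tx < k; ++tx) {
          int ix = ox + tx - pad; if (ix < 0 || ix >= W) continue;
          for (int ty = 0; ty < k; ++ty) {
            int iy = oy + ty - pad; if (iy < 0 || iy >= H) continue;
            for (int tz = 0; tz < k; ++tz) {
              int iz = oz + tz - pad; if (iz < 0 || iz >= D) continue;
              size_t xoff = (size_t)cin * (iz + (size_t)D * (iy + (size_t)H * ix));
              const double* xv = xp + xoff;
              double* gxv = gxp + xoff;
              size_t woff = (size_t)cout * cin * (tz + (size_t)k * (ty + (size_t)k * tx));
              const double* wt = wp + woff;
              double* gwt = gwp + woff;
              for (int ci = 0; ci < cin; ++ci) {
                const double xvci = xv[ci];
                const double* wcol = wt + (size_t)cout * ci;
                double* gwcol = gwt + (size_t)cout * ci;
                double gacc = 0.0;
                for (int c = 0; c < cout; ++c) {
                  const double g = gv[c];
                  gacc += wcol[c] * g;
                  gwcol[c] += xvci * g;
                }
                gxv[ci] += gacc;
              }
            }
          }
        }
      }
  gx.attr("dim") = IntegerVector::create(cin, D, H, W);
  gw.attr("dim") = IntegerVector::create(cout, cin, k, k, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
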