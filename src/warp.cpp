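#include <Rcpp.h>
using namespace Rcpp;

// Pull-warp with bilinear interpolation: out(x, y) = img(M (x, y)) for every
// output pixel, 1-based pixel-centre coordinates, x along columns, y along
// rows. Pixels sampling outside the input are set to `fill` and flagged
// invalid.
// [[Rcpp::export(name = ".warp_affine_cpp")]]
NumericMatrix warp_affine_cpp(const NumericMatrix& img,
                              const NumericMatrix& M, double fill) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  LogicalMatrix valid(h, w);
  const double a11 = M(0, 0), a12 = M(0, 1), tx = M(0, 2);
  const double a21 = M(1, 0), a22 = M(1, 1), ty = M(1, 2);
  for (int x = 0; x < w; ++x) {
    const double xc = x + 1.0;
    for (int y = 0; y < h; ++y) {
      const double yc = y + 1.0;
      const double u = a11 * xc + a12 * yc + tx;
      const double v = a21 * xc + a22 * yc + ty;
      const int x0 = (int)std::floor(u), y0 = (int)std::floor(v);
      if (x0 >= 1 && x0 <= w - 1 && y0 >= 1 && y0 <= h - 1) {
        const double fx = u - x0, fy = v - y0;
        const double i00 = img(y0 - 1, x0 - 1), i10 = img(y0, x0 - 1);
        const double i01 = img(y0 - 1, x0), i11 = img(y0, x0);
        out(y, x) = (1 - fx) * ((1 - fy) * i00 + fy * i10) +
                    fx * ((1 - fy) * i01 + fy * i11);
        valid(y, x) = true;
      } else {
        out(y, x) = fill;
        valid(y, x) = false;
      }
    }
  }
  out.attr("valid") = valid;
  return out;
}
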