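#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat (ball-shaped) structuring
// element. Heights are in the same intensity units as the image (grey
// levels); borders are handled by edge replication so smooth gradients are
// removed cleanly up to the image boundary.
namespace {

struct BallSE {
  std::vector<int> dx, dy;
  std::vector<double> h;
};

BallSE make_ball(int radius) {
  BallSE se;
  const double r2 = static_cast<double>(radius) * radius;
  for (int dx = -radius; dx <= radius; ++dx) {
    for (int dy = -radius; dy <= radius; ++dy) {
      const double d2 = static_cast<double>(dx) * dx + static_cast<double>(dy) * dy;
      if (d2 <= r2) {
        se.dx.push_back(dx);
        se.dy.push_back(dy);
        se.h.push_back(std::sqrt(r2 - d2));
      }
    }
  }
  return se;
}

NumericMatrix morph(const NumericMatrix& img, int radius, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  BallSE se = make_ball(radius);
  const int n = static_cast<int>(se.dx.size());
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int t = 0; t < n; ++t) {
        int ii = i + se.dx[t];
        int jj = j + se.dy[t];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        const double v = erode ? img(ii, jj) - se.h[t] : img(ii, jj) + se.h[t];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".ball_erode")]]
NumericMatrix ball_erode(NumericMatrix img, int radius) {
  return morph(img, radius, true);
}

// [[Rcpp::export(name = ".ball_dilate")]]
NumericMatrix ball_dilate(NumericMatrix img, int radius) {
  return morph(img, radius, false);
}
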