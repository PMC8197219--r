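// 3D convolution kernels for the dense-block UNET.
//
// Tensor layout is channel-first column-major: x has dim (C, X, Y, Z) so the
// channel index is fastest and the inner reduction over input channels runs
// over contiguous memory. Weights have dim (C_in, C_out, K, K, K) for the
// same reason. Zero padding of (K-1)/2 keeps spatial shape ("same").

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int c, int i, int j, int k, int C, int X, int Y) {
  return c + (R_xlen_t)C * (i + (R_xlen_t)X * (j + (R_xlen_t)Y * k));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector xdim, int c_out, int ksize) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int K = ksize, P = (K - 1) / 2;
  NumericVector y((R_xlen_t)c_out * X * Y * Z);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();

  for (int kz = 0; kz < Z; ++kz)
    for (int ky = 0; ky < Y; ++ky)
      for (int kx = 0; kx < X; ++kx) {
        R_xlen_t yo = (R_xlen_t)c_out * (kx + (R_xlen_t)X * (ky + (R_xlen_t)Y * kz));
        for (int co = 0; co < c_out; ++co) py[yo + co] = pb[co];
        for (int dz = 0; dz < K; ++dz) {
          int iz = kz + dz - P;
          if (iz < 0 || iz >= Z) continue;
          for (int dy = 0; dy < K; ++dy) {
            int iy = ky + dy - P;
            if (iy < 0 || iy >= Y) continue;
            for (int dx = 0; dx < K; ++dx) {
              int ix = kx + dx - P;
              if (ix < 0 || ix >= X) continue;
              const double *xi = px + idx4(0, ix, iy, iz, C, X, Y);
              const double *wk = pw + (R_xlen_t)C * c_out *
                (dx + (R_xlen_t)K * (dy + (R_xlen_t)K * dz));
              for (int co = 0; co < c_out; ++co) {
                const double *wc = wk + (R_xlen_t)C * co;
                double acc = 0.0;
                for (int ci = 0; ci < C; ++ci) acc += xi[ci] * wc[ci];
                py[yo + co] += acc;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(c_out, X, Y, Z);
  return y;
}

// Fused backward pass: returns grad wrt input, weights and bias.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                IntegerVector xdim, int c_out, int ksize) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int K = ksize, P = (K - 1) / 2;
  NumericVector gx((R_xlen_t)C * X * Y * Z);
  NumericVector gw(w.size());
  NumericVector gb(c_out);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int kz = 0; kz < Z; ++kz)
    for (int ky = 0; ky < Y; ++ky)
      for (int kx = 0; kx < X; ++kx) {
        R_xlen_t yo = (R_xlen_t)c_out * (kx + (R_xlen_t)X * (ky + (R_xlen_t)Y * kz));
        for (int co = 0; co < c_out; ++co) pgb[co] += pgy[yo + co];
        for (int dz = 0; dz < K; ++dz) {
          int iz = kz + dz - P;
          if (iz < 0 || iz >= Z) continue;
          for (int dy = 0; dy < K; ++dy) {
            int iy = ky + dy - P;
            if (iy < 0 || iy >= Y) continue;
            for (int dx = 0; dx < K; ++dx) {
              int ix = kx + dx - P;
              if (ix < 0 || ix >= X) continue;
              R_xlen_t xo = idx4(0, ix, iy, iz, C, X, Y);
              R_xlen_t wo = (R_xlen_t)C * c_out *
                (dx + (R_xlen_t)K * (dy + (R_xlen_t)K * dz));
              for (int co = 0; co < c_out; ++co) {
                const double g = pgy[yo + co];
                if (g == 0.0) continue;
                const double *wc = pw + wo + (R_xlen_t)C * co;
                double *gwc = pgw + wo + (R_xlen_t)C * co;
                const double *xi = px + xo;
                double *gxi = pgx + xo;
                for (int ci = 0; ci < C; ++ci) {
                  gxi[ci] += wc[ci] * g;
                  gwc[ci] += xi[ci] * g;
                }
              }
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
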