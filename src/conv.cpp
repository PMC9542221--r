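#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D convolution with "same" zero padding on batched R arrays, formulated
// as im2col + GEMM so the heavy lifting runs in BLAS. Layouts are
// column-major: images (H, W, C, N), weights (kh, kw, Cin, Cout). Batches
// here are small (tens of 32-64 px slices, few channels); single-threaded
// BLAS keeps results bitwise deterministic.

static arma::mat im2col(const double *x, int H, int W, int Ci, int N,
                        int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const arma::uword rows = (arma::uword)H * W * N;
  arma::mat out(rows, (arma::uword)kh * kw * Ci, arma::fill::zeros);
  for (int ci = 0; ci < Ci; ++ci)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int di = u - ph, dj = v - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        double *col = out.colptr(((arma::uword)ci * kw + v) * kh + u);
        for (int n = 0; n < N; ++n) {
          const double *xs = x + ((arma::uword)n * Ci + ci) * H * W;
          double *cs = col + (arma::uword)n * H * W;
          for (int j = j0; j < j1; ++j)
            std::copy(xs + (j + dj) * H + i0 + di,
                      xs + (j + dj) * H + i1 + di,
                      cs + j * H + i0);
        }
      }
  return out;
}

// Scatter-add of a column-space gradient back onto the input grid.
static void col2im_add(const arma::mat &gcol, double *gx, int H, int W,
                       int Ci, int N, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Ci; ++ci)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int di = u - ph, dj = v - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const double *col = gcol.colptr(((arma::uword)ci * kw + v) * kh + u);
        for (int n = 0; n < N; ++n) {
          double *gs = gx + ((arma::uword)n * Ci + ci) * H * W;
          const double *cs = col + (arma::uword)n * H * W;
          for (int j = j0; j < j1; ++j) {
            double *g = gs + (j + dj) * H + i0 + di;
            const double *c = cs + j * H + i0;
            for (int i = i0; i < i1; ++i) *g++ += *c++;
          }
        }
      }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  arma::mat xc = im2col(x.begin(), H, W, Ci, N, kh, kw);
  const arma::mat wm(const_cast<double *>(w.begin()),
                     (arma::uword)kh * kw * Ci, Co, false, true);
  arma::mat ym = xc * wm;                      // (H*W*N) x Co
  ym.each_row() += arma::rowvec(const_cast<double *>(b.begin()), Co,
                                false, true);
  NumericVector y(ym.n_elem);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  // reorder (H*W, N) x Co -> (H, W, Co, N)
  const arma::uword HW = (arma::uword)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      std::copy(ym.colptr(co) + (arma::uword)n * HW,
                ym.colptr(co) + (arma::uword)(n + 1) * HW,
                y.begin() + ((arma::uword)n * Co + co) * HW);
  return y;
}

static List bwd_core(const arma::mat &xc, NumericVector w, NumericVector gy,
                     IntegerVector xd) {
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const arma::uword HW = (arma::uword)H * W;
  // gy (H, W, Co, N) -> column space (H*W*N) x Co
  arma::mat gm((arma::uword)H * W * N, Co);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      std::copy(gy.begin() + ((arma::uword)n * Co + co) * HW,
                gy.begin() + ((arma::uword)n * Co + co + 1) * HW,
                gm.colptr(co) + (arma::uword)n * HW);
  const arma::mat wm(const_cast<double *>(w.begin()),
                     (arma::uword)kh * kw * Ci, Co, false, true);
  arma::mat gwm = xc.t() * gm;                 // (kh*kw*Ci) x Co
  arma::rowvec gbv = arma::sum(gm, 0);
  arma::mat gcol = gm * wm.t();                // (H*W*N) x (kh*kw*Ci)
  NumericVector gx((arma::uword)H * W * Ci * N), gw(w.size()), gb(Co);
  gx.attr("dim") = xd; gw.attr("dim") = wd;
  col2im_add(gcol, gx.begin(), H, W, Ci, N, kh, kw);
  std::copy(gwm.begin(), gwm.end(), gw.begin());
  std::copy(gbv.begin(), gbv.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::mat xc = im2col(x.begin(), xd[0], xd[1], xd[2], xd[3], wd[0], wd[1]);
  return bwd_core(xc, w, gy, xd);
}

// Workspace variants for training loops: the forward pass hands back its
// im2col matrix so the backward pass need not rebuild it.
// [[Rcpp::export(name = ".conv2d_fwd_ws")]]
List conv2d_fwd_ws(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  arma::mat xc = im2col(x.begin(), H, W, Ci, N, kh, kw);
  const arma::mat wm(const_cast<double *>(w.begin()),
                     (arma::uword)kh * kw * Ci, Co, false, true);
  arma::mat ym = xc * wm;
  ym.each_row() += arma::rowvec(const_cast<double *>(b.begin()), Co,
                                false, true);
  NumericVector y(ym.n_elem);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const arma::uword HW = (arma::uword)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      std::copy(ym.colptr(co) + (arma::uword)n * HW,
                ym.colptr(co) + (arma::uword)(n + 1) * HW,
                y.begin() + ((arma::uword)n * Co + co) * HW);
  return List::create(_["y"] = y, _["xc"] = wrap(xc),
                      _["xdim"] = xd);
}

// [[Rcpp::export(name = ".conv2d_bwd_ws")]]
List conv2d_bwd_ws(NumericMatrix xc, IntegerVector xdim, NumericVector w,
                   NumericVector gy) {
  const arma::mat xcm(xc.begin(), xc.nrow(), xc.ncol(), false, true);
  return bwd_core(xcm, w, gy, xdim);
}
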