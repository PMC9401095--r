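// Core tensor primitives for the dual-pipeline WCE network.
//
// Feature maps are arma::cube (H x W x C), matching R arrays dim c(H, W, C).
// Convolution weights arrive as a (kh*kw*Cin) x Cout matrix whose row index
// is ordered (dy fastest, then dx, then cin) -- i.e. matrix(W4d, nrow =
// kh*kw*cin) of an R array dim c(kh, kw, cin, cout).
//
// Padding follows the "same" rule with output dims ceil(in/stride); when the
// total pad is odd the extra pixel goes bottom/right (TF convention), which
// is what makes the even fusion kernels (8, 9, 10) well defined.
//
// im2col is chunked over output columns so the scratch buffer never exceeds
// ~64 MB regardless of input size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const uword CHUNK_ELEMS = 8u * 1024u * 1024u;  // doubles per im2col buffer

static inline void same_pad(int in, int k, int s, int& out, int& p0) {
  out = (in + s - 1) / s;
  int total = (out - 1) * s + k - in;
  if (total < 0) total = 0;
  p0 = total / 2;  // floor: extra pad lands bottom/right
}

// Fill the im2col buffer for output columns [j0, j1).
static void fill_cols(mat& cols, const cube& x, int kh, int kw, int s,
                      int pt, int pl, int Ho, int j0, int j1) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int nj = j1 - j0;
  cols.zeros();
  for (int c = 0; c < Cin; ++c) {
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const uword kidx = (uword)dy + (uword)kh * ((uword)dx + (uword)kw * c);
        double* col = cols.colptr(kidx);
        for (int jo = 0; jo < nj; ++jo) {
          const int jj = (j0 + jo) * s - pl + dx;
          if (jj < 0 || jj >= W) continue;
          const double* src = x.slice(c).colptr(jj);
          double* dst = col + (uword)jo * Ho;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * s - pt + dy;
            if (ii >= 0 && ii < H) dst[io] = src[ii];
          }
        }
      }
    }
  }
}

// Scatter-add the col-space gradient back into image space (col2im).
static void scatter_cols(cube& gx, const mat& gcols, int kh, int kw, int s,
                         int pt, int pl, int Ho, int j0, int j1) {
  const int H = gx.n_rows, W = gx.n_cols, Cin = gx.n_slices;
  const int nj = j1 - j0;
  for (int c = 0; c < Cin; ++c) {
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const uword kidx = (uword)dy + (uword)kh * ((uword)dx + (uword)kw * c);
        const double* col = gcols.colptr(kidx);
        for (int jo = 0; jo < nj; ++jo) {
          const int jj = (j0 + jo) * s - pl + dx;
          if (jj < 0 || jj >= W) continue;
          double* dst = gx.slice(c).colptr(jj);
          const double* src = col + (uword)jo * Ho;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * s - pt + dy;
            if (ii >= 0 && ii < H) dst[ii] += src[io];
          }
        }
      }
    }
  }
}

static inline int chunk_cols(int Ho, uword K) {
  uword per_col = (uword)Ho * K;
  int nc = per_col == 0 ? 1 : (int)(CHUNK_ELEMS / per_col);
  return nc < 1 ? 1 : nc;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  const uword K = (uword)kh * kw * Cin;
  if (W.n_rows != K) Rcpp::stop("weight rows != kh*kw*cin");
  int Ho, Wo, pt, pl;
  same_pad(H, kh, stride, Ho, pt);
  same_pad(Wd, kw, stride, Wo, pl);
  cube out(Ho, Wo, Cout);
  const int nc = chunk_cols(Ho, K);
  mat cols;
  for (int j0 = 0; j0 < Wo; j0 += nc) {
    const int j1 = std::min(Wo, j0 + nc);
    const uword n = (uword)Ho * (j1 - j0);
    cols.set_size(n, K);
    fill_cols(cols, x, kh, kw, stride, pt, pl, Ho, j0, j1);
    mat oc = cols * W;  // n x Cout
    for (int c = 0; c < Cout; ++c)
      std::memcpy(out.slice(c).colptr(j0), oc.colptr(c), n * sizeof(double));
  }
  for (int c = 0; c < Cout; ++c) out.slice(c) += b(c);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gout, int kh, int kw, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  const uword K = (uword)kh * kw * Cin;
  int Ho, Wo, pt, pl;
  same_pad(H, kh, stride, Ho, pt);
  same_pad(Wd, kw, stride, Wo, pl);
  if ((int)gout.n_rows != Ho || (int)gout.n_cols != Wo ||
      (int)gout.n_slices != Cout)
    Rcpp::stop("gout shape mismatch");
  cube gx(H, Wd, Cin, fill::zeros);
  mat gW(K, Cout, fill::zeros);
  vec gb(Cout);
  for (int c = 0; c < Cout; ++c) gb(c) = accu(gout.slice(c));
  const int nc = chunk_cols(Ho, K);
  mat cols, G;
  for (int j0 = 0; j0 < Wo; j0 += nc) {
    const int j1 = std::min(Wo, j0 + nc);
    const uword n = (uword)Ho * (j1 - j0);
    cols.set_size(n, K);
    fill_cols(cols, x, kh, kw, stride, pt, pl, Ho, j0, j1);
    G.set_size(n, Cout);
    for (int c = 0; c < Cout; ++c)
      std::memcpy(G.colptr(c), gout.slice(c).colptr(j0), n * sizeof(double));
    gW += cols.t() * G;
    mat gcols = G * W.t();  // n x K
    scatter_cols(gx, gcols, kh, kw, stride, pt, pl, Ho, j0, j1);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Input-space gradient alone: this is the forward pass of the transposed
// convolution (output shape Hin x Win fixed by the caller).
// [[Rcpp::export]]
arma::cube cpp_conv2d_gx(const arma::mat& W, const arma::cube& gout, int Hin,
                         int Win, int Cin, int kh, int kw, int stride) {
  const int Cout = W.n_cols;
  const uword K = (uword)kh * kw * Cin;
  if (W.n_rows != K) Rcpp::stop("weight rows != kh*kw*cin");
  int Ho, Wo, pt, pl;
  same_pad(Hin, kh, stride, Ho, pt);
  same_pad(Win, kw, stride, Wo, pl);
  if ((int)gout.n_rows != Ho || (int)gout.n_cols != Wo ||
      (int)gout.n_slices != Cout)
    Rcpp::stop("gout shape mismatch");
  cube gx(Hin, Win, Cin, fill::zeros);
  const int nc = chunk_cols(Ho, K);
  mat G;
  for (int j0 = 0; j0 < Wo; j0 += nc) {
    const int j1 = std::min(Wo, j0 + nc);
    const uword n = (uword)Ho * (j1 - j0);
    G.set_size(n, Cout);
    for (int c = 0; c < Cout; ++c)
      std::memcpy(G.colptr(c), gout.slice(c).colptr(j0), n * sizeof(double));
    mat gcols = G * W.t();
    scatter_cols(gx, gcols, kh, kw, stride, pt, pl, Ho, j0, j1);
  }
  return gx;
}

// Weight gradient alone (used for the transposed convolution's weights,
// with the roles of the two spaces swapped by the caller).
// [[Rcpp::export]]
arma::mat cpp_conv2d_gw(const arma::cube& x, const arma::cube& gout, int kh,
                        int kw, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  const uword K = (uword)kh * kw * Cin;
  int Ho, Wo, pt, pl;
  same_pad(H, kh, stride, Ho, pt);
  same_pad(Wd, kw, stride, Wo, pl);
  if ((int)gout.n_rows != Ho || (int)gout.n_cols != Wo)
    Rcpp::stop("gout shape mismatch");
  mat gW(K, Cout, fill::zeros);
  const int nc = chunk_cols(Ho, K);
  mat cols, G;
  for (int j0 = 0; j0 < Wo; j0 += nc) {
    const int j1 = std::min(Wo, j0 + nc);
    const uword n = (uword)Ho * (j1 - j0);
    cols.set_size(n, K);
    fill_cols(cols, x, kh, kw, stride, pt, pl, Ho, j0, j1);
    G.set_size(n, Cout);
    for (int c = 0; c < Cout; ++c)
      std::memcpy(G.colptr(c), gout.slice(c).colptr(j0), n * sizeof(double));
    gW += cols.t() * G;
  }
  return gW;
}

// Depthwise 2-D convolution, channel multiplier 1, same padding.
// W is kh x kw x C (one filter per channel).
// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const arma::cube& x, const arma::cube& W,
                          const arma::vec& b, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int kh = W.n_rows, kw = W.n_cols;
  if ((int)W.n_slices != C) Rcpp::stop("depthwise weight channels != input");
  int Ho, Wo, pt, pl;
  same_pad(H, kh, stride, Ho, pt);
  same_pad(Wd, kw, stride, Wo, pl);
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const mat& ws = W.slice(c);
    mat& os = out.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double acc = b(c);
        for (int dx = 0; dx < kw; ++dx) {
          const int jj = jo * stride - pl + dx;
          if (jj < 0 || jj >= Wd) continue;
          for (int dy = 0; dy < kh; ++dy) {
            const int ii = io * stride - pt + dy;
            if (ii >= 0 && ii < H) acc += xs(ii, jj) * ws(dy, dx);
          }
        }
        os(io, jo) = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bwd(const arma::cube& x, const arma::cube& W,
                          const arma::cube& gout, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int kh = W.n_rows, kw = W.n_cols;
  int Ho, Wo, pt, pl;
  same_pad(H, kh, stride, Ho, pt);
  same_pad(Wd, kw, stride, Wo, pl);
  if ((int)gout.n_rows != Ho || (int)gout.n_cols != Wo ||
      (int)gout.n_slices != C)
    Rcpp::stop("gout shape mismatch");
  cube gx(H, Wd, C, fill::zeros);
  cube gW(kh, kw, C, fill::zeros);
  vec gb(C);
  for (int c = 0; c < C; ++c) {
    gb(c) = accu(gout.slice(c));
    const mat& xs = x.slice(c);
    const mat& ws = W.slice(c);
    const mat& gs = gout.slice(c);
    mat& gxs = gx.slice(c);
    mat& gws = gW.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const double g = gs(io, jo);
        for (int dx = 0; dx < kw; ++dx) {
          const int jj = jo * stride - pl + dx;
          if (jj < 0 || jj >= Wd) continue;
          for (int dy = 0; dy < kh; ++dy) {
            const int ii = io * stride - pt + dy;
            if (ii < 0 || ii >= H) continue;
            gxs(ii, jj) += g * ws(dy, dx);
            gws(dy, dx) += g * xs(ii, jj);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 stride-2 max pooling; even dims required. Returns pooled cube and the
// winning offset code (0..3, column-major within the window) for backprop.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("max-pool requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = xs(2 * io, 2 * jo);
        uword code = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            const double v = xs(2 * io + dy, 2 * jo + dx);
            if (v > best) { best = v; code = dy + 2 * dx; }
          }
        out(io, jo, c) = best;
        idx(io, jo, c) = code;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gout) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  cube gx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const uword code = idx(io, jo, c);
        gx(2 * io + (code % 2), 2 * jo + (code / 2), c) = gout(io, jo, c);
      }
    }
  }
  return gx;
}
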