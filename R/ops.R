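# Thin R wrappers over the C++ tensor primitives plus the elementwise
# activations. All feature maps are plain R arrays dim c(H, W, C).

leaky <- function(x, slope = 0.1) pmax(x, 0) + slope * pmin(x, 0)
leaky_grad <- function(z, slope = 0.1) (z > 0) + slope * (z <= 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3)
    stopf("a feature map must be a rank-3 array (H, W, C)")
  if (!all(is.finite(x))) stopf("feature map contains non-finite entries")
  x
}

# Same-padded convolution (pre-activation). W is (kh, kw, cin, cout).
conv2d <- function(x, W, b, stride = 1L) {
  d <- dim(W)
  if (dim(x)[3] != d[3]) stopf("conv2d: input has %d channels, weights expect %d",
                               dim(x)[3], d[3])
  cpp_conv2d_fwd(x, matrix(W, nrow = d[1] * d[2] * d[3]), as.double(b),
                 d[1], d[2], as.integer(stride))
}

conv2d_bwd <- function(x, W, gout, stride = 1L) {
  d <- dim(W)
  r <- cpp_conv2d_bwd(x, matrix(W, nrow = d[1] * d[2] * d[3]), gout,
                      d[1], d[2], as.integer(stride))
  list(gx = r$gx, gW = array(r$gW, d), gb = as.numeric(r$gb))
}

# Transposed convolution: exact spatial doubling, implemented as the adjoint
# of a stride-2 same-padded convolution mapping (2H, 2W, cout_assoc) ->
# (H, W, cin_assoc). W is stored in the associated conv's layout
# (kh, kw, out_channels, in_channels); bias is per output channel.
tconv2d <- function(x, W, b, hout, wout) {
  d <- dim(W)
  if (dim(x)[3] != d[4]) stopf("tconv2d: input channels mismatch")
  m <- cpp_conv2d_gx(matrix(W, nrow = d[1] * d[2] * d[3]), x,
                     as.integer(hout), as.integer(wout), d[3], d[1], d[2], 2L)
  for (c in seq_len(d[3])) m[, , c] <- m[, , c] + b[c]
  m
}

tconv2d_bwd <- function(x, W, gout) {
  d <- dim(W)
  gx <- cpp_conv2d_fwd(gout, matrix(W, nrow = d[1] * d[2] * d[3]),
                       numeric(d[4]), d[1], d[2], 2L)
  gW <- array(cpp_conv2d_gw(gout, x, d[1], d[2], 2L), d)
  gb <- vapply(seq_len(d[3]), function(c) sum(gout[, , c]), 0)
  list(gx = gx, gW = gW, gb = gb)
}

dwconv2d <- function(x, W, b, stride = 1L)
  cpp_dwconv_fwd(x, W, as.double(b), as.integer(stride))

dwconv2d_bwd <- function(x, W, gout, stride = 1L) {
  r <- cpp_dwconv_bwd(x, W, gout, as.integer(stride))
  list(gx = r$gx, gW = r$gW, gb = as.numeric(r$gb))
}

maxpool2 <- function(x) cpp_maxpool2_fwd(x)
maxpool2_bwd <- function(idx, gout) cpp_maxpool2_bwd(idx, gout)

#' Convolution block: same-padded convolution + LeakyReLU
#'
#' The basic non-linear transformation of both pipelines: a `(k, k)` filter
#' bank convolved with stride `s` under "same" padding (output spatial dims
#' `ceiling(input/stride)`; for even kernels the extra pad pixel falls
#' bottom/right), followed by a LeakyReLU.
#'
#' @param x Feature map, array `(H, W, C_in)`.
#' @param W Weights `(kh, kw, C_in, C_out)`.
#' @param b Bias, length `C_out`.
#' @param stride Positive integer stride.
#' @param slope LeakyReLU negative slope.
#' @return Feature map `(ceil(H/s), ceil(W/s), C_out)`.
#' @export
conv_block <- function(x, W, b, stride = 1L, slope = 0.1) {
  x <- as_feature_map(x)
  if (stride < 1 || dim(W)[1] < 1) stopf("kernel and stride must be >= 1")
  leaky(conv2d(x, W, b, stride), slope)
}

#' Global average pooling
#'
#' Per-channel arithmetic mean over both spatial axes, collapsing an
#' `(H, W, C)` feature map to a length-`C` vector.
#'
#' @param x Feature map, array `(H, W, C)`.
#' @return Numeric vector of length `C`.
#' @export
global_average_pool <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

gap_bwd <- function(g, d) {
  array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# Dense layer: W is (d_in, d_out).
dense_fwd <- function(x, W, b) drop(crossprod(W, x)) + b
dense_bwd <- function(x, W, gz) {
  list(gx = drop(W %*% gz), gW = outer(x, gz), gb = gz)
}

# He-style initializers; all randomness must be wrapped in with_seed by
# the caller.
init_conv <- function(kh, kw, cin, cout)
  list(W = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
init_dw <- function(k, C)
  list(W = array(rnorm(k * k * C, sd = sqrt(2 / (k * k))), c(k, k, C)),
       b = numeric(C))
init_tconv <- function(k, cin, cout)  # stored in associated-conv layout
  list(W = array(rnorm(k * k * cout * cin, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cout, cin)),
       b = numeric(cout))
init_dense <- function(din, dout)
  list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
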