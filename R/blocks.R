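# The two bespoke blocks of the network (volumetric attention, pyramid
# feature extraction) plus the encoder stage and decision head. Each block
# has an internal *_fwd returning a cache and a *_bwd consuming it; the
# exported spec-level wrappers sit at the bottom.

# ---- Volumetric Attention Mechanism ---------------------------------------
# x_r (H, W, C) -> squeeze: 3x3 stride-2 conv to C/2 channels (spatial
# condensation); depthwise 3x3 refinement (channel-wise filtering); their
# elementwise sum x_v; a 3x3 stride-2 transposed conv back to (H, W, 1),
# LeakyReLU, sigmoid -> mask in [0,1]; output F = x_r + x_r * mask.
vam_fwd <- function(vp, x_r, slope = 0.1) {
  d <- dim(x_r)
  if (d[1] %% 2 || d[2] %% 2)
    stopf("attention block requires even spatial dims, got %dx%d", d[1], d[2])
  if (d[3] %% 2) stopf("attention block requires an even channel count")
  a_s <- conv2d(x_r, vp$squeeze$W, vp$squeeze$b, 2L)
  x_s <- leaky(a_s, slope)
  a_d <- dwconv2d(x_s, vp$dw$W, vp$dw$b, 1L)
  x_c <- leaky(a_d, slope)
  x_v <- x_s + x_c
  t_pre <- tconv2d(x_v, vp$up$W, vp$up$b, d[1], d[2])
  m_pre <- leaky(t_pre, slope)
  mask <- sigmoid(m_pre)
  f <- x_r * (1 + as.vector(mask))  # single-channel mask broadcast over C
  list(f = f, mask = mask,
       cache = list(x_r = x_r, a_s = a_s, x_s = x_s, a_d = a_d, x_v = x_v,
                    t_pre = t_pre, mask = mask, d = d))
}

vam_bwd <- function(vp, cache, gf, slope = 0.1) {
  d <- cache$d
  hw <- d[1] * d[2]
  mvec <- as.vector(cache$mask)
  g_xr <- gf * (1 + mvec)
  g_mask <- array(rowSums(matrix(gf * cache$x_r, hw, d[3])), c(d[1], d[2], 1L))
  g_mpre <- g_mask * cache$mask * (1 - cache$mask)
  g_tpre <- g_mpre * leaky_grad(cache$t_pre, slope)
  tb <- tconv2d_bwd(cache$x_v, vp$up$W, g_tpre)
  g_xv <- tb$gx
  g_ad <- g_xv * leaky_grad(cache$a_d, slope)
  db <- dwconv2d_bwd(cache$x_s, vp$dw$W, g_ad, 1L)
  g_xs <- g_xv + db$gx  # x_v = x_s + x_c: direct path plus depthwise path
  g_as <- g_xs * leaky_grad(cache$a_s, slope)
  sb <- conv2d_bwd(cache$x_r, vp$squeeze$W, g_as, 2L)
  list(g_xr = g_xr + sb$gx,
       gp = list(squeeze = list(W = sb$gW, b = sb$gb),
                 dw = list(W = db$gW, b = db$gb),
                 up = list(W = tb$gW, b = tb$gb)))
}

init_vam <- function(C) {
  half <- C %/% 2L
  list(squeeze = init_conv(3L, 3L, C, half),
       dw = init_dw(3L, half),
       up = init_tconv(3L, half, 1L))
}

# ---- Encoder stage --------------------------------------------------------
# Two same-padded 3x3 conv blocks (channel rule applied at the first),
# attention, then 2x2 stride-2 max-pool. The pre-attention map x_r is the
# registered tap for the regional pipeline.
encoder_fwd <- function(ep, x, slope = 0.1) {
  a1 <- conv2d(x, ep$conv1$W, ep$conv1$b, 1L)
  r1 <- leaky(a1, slope)
  a2 <- conv2d(r1, ep$conv2$W, ep$conv2$b, 1L)
  x_r <- leaky(a2, slope)
  v <- vam_fwd(ep$vam, x_r, slope)
  mp <- maxpool2(v$f)
  list(y = mp$out, x_r = x_r, mask = v$mask,
       cache = list(x = x, a1 = a1, r1 = r1, a2 = a2,
                    vam = v$cache, poolidx = mp$idx))
}

encoder_bwd <- function(ep, cache, gy, g_xr_extra = NULL, slope = 0.1) {
  gf <- maxpool2_bwd(cache$poolidx, gy)
  vb <- vam_bwd(ep$vam, cache$vam, gf, slope)
  g_xr <- vb$g_xr
  if (!is.null(g_xr_extra)) g_xr <- g_xr + g_xr_extra
  g_a2 <- g_xr * leaky_grad(cache$a2, slope)
  c2 <- conv2d_bwd(cache$r1, ep$conv2$W, g_a2, 1L)
  g_a1 <- c2$gx * leaky_grad(cache$a1, slope)
  c1 <- conv2d_bwd(cache$x, ep$conv1$W, g_a1, 1L)
  list(gx = c1$gx,
       gp = list(conv1 = list(W = c1$gW, b = c1$gb),
                 conv2 = list(W = c2$gW, b = c2$gb),
                 vam = vb$gp))
}

init_encoder <- function(cin, cout) {
  list(conv1 = init_conv(3L, 3L, cin, cout),
       conv2 = init_conv(3L, 3L, cout, cout),
       vam = init_vam(cout))
}

# ---- Pyramid Feature Extractor --------------------------------------------
# Four parallel conv blocks with kernels 1/3/5/7 (rho channels each);
# adjacent pairs concatenated to 2*rho channels; each pair fused by a conv
# block with kernels 8/9/10; the three fused maps concatenated (6*rho) and
# fused to 2*rho by a kernel-11 conv block. Spatial dims preserved.
PFE_PAR_KERNELS <- c(1L, 3L, 5L, 7L)
PFE_FUSE_KERNELS <- c(8L, 9L, 10L)
PFE_FINAL_KERNEL <- 11L

cat3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        c(d[1], d[2], sum(vapply(xs, function(a) dim(a)[3], 0L))))
}

pfe_fwd <- function(pp, x, slope = 0.1) {
  a <- r <- vector("list", 4L)
  for (j in 1:4) {
    a[[j]] <- conv2d(x, pp$par[[j]]$W, pp$par[[j]]$b, 1L)
    r[[j]] <- leaky(a[[j]], slope)
  }
  pr <- fz <- fa <- vector("list", 3L)
  for (j in 1:3) {
    pr[[j]] <- cat3(r[[j]], r[[j + 1]])
    fa[[j]] <- conv2d(pr[[j]], pp$fuse[[j]]$W, pp$fuse[[j]]$b, 1L)
    fz[[j]] <- leaky(fa[[j]], slope)
  }
  cc <- cat3(fz[[1]], fz[[2]], fz[[3]])
  fin_a <- conv2d(cc, pp$final$W, pp$final$b, 1L)
  P <- leaky(fin_a, slope)
  list(P = P, cache = list(x = x, a = a, r = r, pr = pr, fa = fa,
                           cc = cc, fin_a = fin_a))
}

pfe_bwd <- function(pp, cache, gP, slope = 0.1) {
  rho2 <- dim(gP)[3]
  g_fin <- gP * leaky_grad(cache$fin_a, slope)
  fb <- conv2d_bwd(cache$cc, pp$final$W, g_fin, 1L)
  g_r <- lapply(cache$r, function(z) array(0, dim(z)))
  gp_fuse <- vector("list", 3L)
  for (j in 1:3) {
    g_fz <- fb$gx[, , ((j - 1) * rho2 + 1):(j * rho2), drop = FALSE]
    g_fa <- g_fz * leaky_grad(cache$fa[[j]], slope)
    cb <- conv2d_bwd(cache$pr[[j]], pp$fuse[[j]]$W, g_fa, 1L)
    gp_fuse[[j]] <- list(W = cb$gW, b = cb$gb)
    half <- rho2 %/% 2L
    g_r[[j]] <- g_r[[j]] + cb$gx[, , 1:half, drop = FALSE]
    g_r[[j + 1]] <- g_r[[j + 1]] + cb$gx[, , (half + 1):rho2, drop = FALSE]
  }
  gx <- array(0, dim(cache$x))
  gp_par <- vector("list", 4L)
  for (j in 1:4) {
    g_a <- g_r[[j]] * leaky_grad(cache$a[[j]], slope)
    pb <- conv2d_bwd(cache$x, pp$par[[j]]$W, g_a, 1L)
    gp_par[[j]] <- list(W = pb$gW, b = pb$gb)
    gx <- gx + pb$gx
  }
  list(gx = gx, gp = list(par = gp_par, fuse = gp_fuse,
                          final = list(W = fb$gW, b = fb$gb)))
}

init_pfe <- function(cin, rho) {
  list(par = lapply(PFE_PAR_KERNELS, function(k) init_conv(k, k, cin, rho)),
       fuse = lapply(PFE_FUSE_KERNELS,
                     function(k) init_conv(k, k, 2L * rho, 2L * rho)),
       final = init_conv(PFE_FINAL_KERNEL, PFE_FINAL_KERNEL, 6L * rho, 2L * rho))
}

# ---- Decision head --------------------------------------------------------
head_fwd <- function(hp, z, slope = 0.1, head_mode = "softmax") {
  a1 <- dense_fwd(z, hp$d1$W, hp$d1$b)
  h1 <- leaky(a1, slope)
  a2 <- dense_fwd(h1, hp$d2$W, hp$d2$b)
  h2 <- leaky(a2, slope)
  logits <- dense_fwd(h2, hp$d3$W, hp$d3$b)
  probs <- if (head_mode == "sigmoid_binary") sigmoid(logits) else softmax(logits)
  list(probs = probs, logits = logits,
       cache = list(z = z, a1 = a1, h1 = h1, a2 = a2, h2 = h2))
}

head_bwd <- function(hp, cache, dlogits, slope = 0.1) {
  d3 <- dense_bwd(cache$h2, hp$d3$W, dlogits)
  g_a2 <- d3$gx * leaky_grad(cache$a2, slope)
  d2 <- dense_bwd(cache$h1, hp$d2$W, g_a2)
  g_a1 <- d2$gx * leaky_grad(cache$a1, slope)
  d1 <- dense_bwd(cache$z, hp$d1$W, g_a1)
  list(gz = d1$gx,
       gp = list(d1 = list(W = d1$gW, b = d1$gb),
                 d2 = list(W = d2$gW, b = d2$gb),
                 d3 = list(W = d3$gW, b = d3$gb)))
}

init_head <- function(din, dense_sizes, num_out) {
  list(d1 = init_dense(din, dense_sizes[1]),
       d2 = init_dense(dense_sizes[1], dense_sizes[2]),
       d3 = init_dense(dense_sizes[2], num_out))
}

# ---- Exported spec-level wrappers -----------------------------------------

#' Volumetric attention forward pass
#'
#' Condenses a feature map spatially (strided convolution to half the
#' channels) and channel-wise (depthwise refinement), sums both condensations,
#' upsamples through an exactly-doubling transposed convolution to a
#' single-channel map, and squashes it through LeakyReLU + sigmoid into an
#' attention mask in `[0, 1]`. The block output is the residually enhanced
#' input `f = x_r * (1 + mask)` with the mask broadcast over all channels.
#'
#' @param params Parameter list with elements `squeeze`, `dw`, `up`
#'   (see [init_vam_params()]).
#' @param x_r Feature map `(H, W, C)`; `H`, `W` and `C` must be even.
#' @param slope LeakyReLU negative slope.
#' @return List with `f` (enhanced map, same shape as `x_r`) and `mask`
#'   (`(H, W, 1)` array in `[0, 1]`).
#' @export
vam_forward <- function(params, x_r, slope = 0.1) {
  v <- vam_fwd(params, as_feature_map(x_r), slope)
  list(f = v$f, mask = v$mask)
}

#' Initialize volumetric-attention parameters
#'
#' @param channels Even channel count `C` of the feature map to attend over.
#' @param seed Seed for the weight draw.
#' @return Parameter list accepted by [vam_forward()].
#' @export
init_vam_params <- function(channels, seed = 1L) {
  if (channels %% 2) stopf("channels must be even")
  with_seed(seed, init_vam(as.integer(channels)))
}

#' Encoder stage forward pass
#'
#' Two same-padded 3x3 convolution blocks (the first applying the channel
#' rule), volumetric attention, then a 2x2 stride-2 max-pool. Returns the
#' pooled output, the pre-attention registered tap forwarded to the regional
#' pipeline, and the attention mask.
#'
#' @param params Parameter list with `conv1`, `conv2`, `vam`.
#' @param x Input feature map `(H, W, C_in)` with even `H`, `W`.
#' @param slope LeakyReLU negative slope.
#' @return List with `y` (`(H/2, W/2, C)`), `x_r_tap` (`(H, W, C)`) and
#'   `mask` (`(H, W, 1)`).
#' @export
encoder_forward <- function(params, x, slope = 0.1) {
  e <- encoder_fwd(params, as_feature_map(x), slope)
  list(y = e$y, x_r_tap = e$x_r, mask = e$mask)
}

#' Pyramid feature extraction forward pass
#'
#' Parallel kernels 1/3/5/7 at `rho` channels, adjacent-pair concatenation,
#' fusion with kernels 8/9/10, concatenation to `6*rho` channels and a final
#' kernel-11 fusion to `2*rho` channels. Spatial dimensions are preserved.
#'
#' @param params Parameter list (see [init_pfe_params()]).
#' @param x_r Registered tap `(H, W, C)`.
#' @param slope LeakyReLU negative slope.
#' @return Feature map `(H, W, 2*rho)`.
#' @export
pfe_forward <- function(params, x_r, slope = 0.1) {
  pfe_fwd(params, as_feature_map(x_r), slope)$P
}

#' Initialize pyramid-feature-extractor parameters
#'
#' @param channels Input channel count of the registered tap.
#' @param rho Pyramid width (channels of each parallel branch).
#' @param seed Seed for the weight draw.
#' @return Parameter list accepted by [pfe_forward()].
#' @export
init_pfe_params <- function(channels, rho = 16L, seed = 1L) {
  with_seed(seed, init_pfe(as.integer(channels), as.integer(rho)))
}

#' Decision head forward pass
#'
#' Concatenates the pooled compression vector with the pooled pyramid vectors
#' (ascending stage order), applies two dense + LeakyReLU layers and a final
#' dense layer with softmax (or a single sigmoid unit in binary mode).
#'
#' @param params Parameter list with `d1`, `d2`, `d3`.
#' @param y5_vec Pooled compression-pipeline vector.
#' @param p_vecs List of pooled pyramid vectors, ascending stage order.
#' @param slope LeakyReLU negative slope.
#' @param head_mode `"softmax"` or `"sigmoid_binary"`.
#' @return Class-probability vector (`num_classes` entries summing to 1, or a
#'   single sigmoid value).
#' @export
decision_forward <- function(params, y5_vec, p_vecs = list(), slope = 0.1,
                             head_mode = "softmax") {
  z <- c(y5_vec, unlist(p_vecs, use.names = FALSE))
  if (length(z) != nrow(params$d1$W))
    stopf("decision head expects an input of length %d, got %d",
          nrow(params$d1$W), length(z))
  head_fwd(params, z, slope, head_mode)$probs
}
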