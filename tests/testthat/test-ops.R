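# Tensor primitives against brute-force oracles, including the padding
# conventions the pyramid's even kernels rely on.

test_that("same-padded convolution matches the loop oracle across kernels and strides", {
  cases <- list(c(k = 3, s = 1, h = 5, w = 6, ci = 2, co = 3),
                c(k = 1, s = 1, h = 4, w = 4, ci = 3, co = 2),
                c(k = 8, s = 1, h = 6, w = 6, ci = 3, co = 2),  # even kernel
                c(k = 11, s = 1, h = 6, w = 5, ci = 2, co = 2),
                c(k = 3, s = 2, h = 8, w = 8, ci = 4, co = 4),
                c(k = 5, s = 2, h = 7, w = 9, ci = 2, co = 3))
  for (cs in cases) {
    cs <- as.list(unname(cs))
    names(cs) <- c("k", "s", "h", "w", "ci", "co")
    set.seed(sum(unlist(cs)))
    x <- array(rnorm(cs$h * cs$w * cs$ci), c(cs$h, cs$w, cs$ci))
    W <- array(rnorm(cs$k^2 * cs$ci * cs$co), c(cs$k, cs$k, cs$ci, cs$co))
    b <- rnorm(cs$co)
    got <- ratcapsnet:::conv2d(x, W, b, cs$s)
    want <- naive_conv(x, W, b, cs$s)
    expect_equal(dim(got), c(ceiling(cs$h / cs$s), ceiling(cs$w / cs$s), cs$co))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("conv_block applies LeakyReLU and preserves same-padding dims", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  W <- array(rnorm(3 * 3 * 3 * 32), c(3, 3, 3, 32))
  b <- rnorm(32)
  out <- conv_block(x, W, b, stride = 1)
  expect_equal(dim(out), c(8, 8, 32))
  out2 <- conv_block(out, array(rnorm(3 * 3 * 32 * 8), c(3, 3, 32, 8)),
                     numeric(8), stride = 2)
  expect_equal(dim(out2), c(4, 4, 8))
  # zero weights and bias give identically zero output (LeakyReLU(0) = 0)
  z <- conv_block(x, array(0, c(3, 3, 3, 4)), numeric(4))
  expect_true(all(z == 0))
  # LeakyReLU: negatives scaled by the slope
  pre <- ratcapsnet:::conv2d(x, W, b, 1)
  expect_equal(out[pre < 0], 0.1 * pre[pre < 0])
  expect_equal(out[pre > 0], pre[pre > 0])
})

test_that("depthwise convolution matches its oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- array(rnorm(6 * 7 * 3), c(6, 7, 3))
    W <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
    b <- rnorm(3)
    expect_equal(ratcapsnet:::dwconv2d(x, W, b, 1),
                 naive_dwconv(x, W, b, 1), tolerance = 1e-12)
  }
})

test_that("max pooling matches its oracle and backward routes to the argmax", {
  set.seed(4)
  x <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  mp <- ratcapsnet:::maxpool2(x)
  expect_equal(mp$out, naive_maxpool2(x), tolerance = 1e-15)
  g <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  gx <- ratcapsnet:::maxpool2_bwd(mp$idx, g)
  expect_equal(sum(gx != 0), length(g))  # one winner per window
  expect_error(ratcapsnet:::maxpool2(array(0, c(5, 6, 1))), "even")
})

test_that("global average pooling equals the brute-force double-loop mean", {
  for (seed in 1:20) {
    x <- rand_map(sample(2:9, 1), sample(2:9, 1), sample(1:5, 1), seed)
    expect_equal(global_average_pool(x), naive_gap(x), tolerance = 1e-12)
  }
  expect_equal(global_average_pool(array(7, c(8, 8, 512))), rep(7, 512))
  expect_equal(global_average_pool(array(c(1, 3, 2, 4), c(2, 2, 1))), 2.5)
})

test_that("transposed convolution doubles spatial dims exactly and is the conv adjoint", {
  set.seed(5)
  for (hw in list(c(4, 4), c(6, 8), c(16, 16))) {
    cin <- 4
    x <- array(rnorm(hw[1] * hw[2] * cin), c(hw[1], hw[2], cin))
    W <- array(rnorm(3 * 3 * 1 * cin), c(3, 3, 1, cin))
    up <- ratcapsnet:::tconv2d(x, W, 0, 2 * hw[1], 2 * hw[2])
    expect_equal(dim(up), c(2 * hw[1], 2 * hw[2], 1))
    # adjoint identity <tconv(x), a> == <x, conv(a)> for random a
    a <- array(rnorm(4 * hw[1] * hw[2]), c(2 * hw[1], 2 * hw[2], 1))
    lhs <- sum(up * a)
    rhs <- sum(x * naive_conv(a, W, numeric(cin), 2))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("convolution backward matches numerical gradients", {
  set.seed(6)
  for (cs in list(c(k = 3, s = 1), c(k = 2, s = 1), c(k = 3, s = 2))) {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    W <- array(rnorm(cs["k"]^2 * 2 * 3), c(cs["k"], cs["k"], 2, 3))
    b <- rnorm(3)
    gout <- array(rnorm(prod(dim(ratcapsnet:::conv2d(x, W, b, cs["s"])))),
                  dim(ratcapsnet:::conv2d(x, W, b, cs["s"])))
    bw <- ratcapsnet:::conv2d_bwd(x, W, gout, cs["s"])
    lossfun <- function(xx, WW, bb) sum(ratcapsnet:::conv2d(xx, WW, bb, cs["s"]) * gout)
    eps <- 1e-6
    for (rep in 1:5) {
      i <- sample(length(x), 1)
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      expect_equal(bw$gx[i], (lossfun(xp, W, b) - lossfun(xm, W, b)) / (2 * eps),
                   tolerance = 1e-5)
      j <- sample(length(W), 1)
      Wp <- W; Wp[j] <- Wp[j] + eps
      Wm <- W; Wm[j] <- Wm[j] - eps
      expect_equal(bw$gW[j], (lossfun(x, Wp, b) - lossfun(x, Wm, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
    expect_equal(bw$gb, vapply(1:3, function(c) sum(gout[, , c]), 0),
                 tolerance = 1e-10)
  }
})
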