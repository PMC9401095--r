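# Block-level and whole-network contracts: channel rule, attention identity,
# shape chain, decision head, parameter counting, gradient flow.

test_that("channel rule: 3 -> n, otherwise doubling", {
  expect_equal(channel_rule(3), 32)
  expect_equal(channel_rule(32), 64)
  expect_equal(channel_rule(256), 512)
  expect_equal(channel_rule(3, n = 8), 8)
  expect_error(channel_rule(0), "positive")
})

test_that("attention block: mask in [0,1] and exact residual identity", {
  for (seed in 1:10) {
    set.seed(seed)
    hw <- sample(c(4, 8, 16), 1)
    C <- sample(c(4, 8), 1)
    vp <- init_vam_params(C, seed = seed + 100)
    x_r <- array(rnorm(hw * hw * C), c(hw, hw, C))
    v <- vam_forward(vp, x_r)
    expect_equal(dim(v$mask), c(hw, hw, 1))
    expect_true(all(v$mask >= 0 & v$mask <= 1))
    expect_equal(v$f, x_r * (1 + as.vector(v$mask)), tolerance = 1e-6)
  }
})

test_that("attention gate closes when the upsampling weights are zero with large negative bias", {
  vp <- init_vam_params(8, seed = 1)
  vp$up$W[] <- 0
  vp$up$b[] <- -200  # LeakyReLU passes -20, sigmoid(-20) ~ 2e-9
  x_r <- rand_map(8, 8, 8, 2)
  v <- vam_forward(vp, x_r)
  expect_lt(max(v$mask), 1e-8)
  expect_equal(v$f, x_r, tolerance = 1e-6)
})

test_that("attention block rejects odd spatial dims", {
  vp <- init_vam_params(4, seed = 1)
  expect_error(vam_forward(vp, array(0, c(7, 8, 4))), "even")
})

test_that("encoder stage: shape contract and registered tap", {
  cfg <- network_config(base_width_n = 8L, num_stages = 3L, pfe_stages = 2:3,
                        pfe_width_rho = 4L, dense_sizes = c(16L, 8L),
                        num_classes = 2L, input_hw = c(32L, 32L))
  m <- assemble_ratcapsnet(cfg, seed = 3)
  x <- rand_map(32, 32, 3, 1)
  e <- encoder_forward(m$params$enc[[1]], x)
  expect_equal(dim(e$x_r_tap), c(32, 32, 8))
  expect_equal(dim(e$y), c(16, 16, 8))
  expect_equal(dim(e$mask), c(32, 32, 1))
  expect_error(encoder_forward(m$params$enc[[1]], rand_map(17, 17, 3, 1)))
})

test_that("whole-network shape chain halves space and doubles channels", {
  cfg <- network_config(base_width_n = 8L, pfe_width_rho = 4L,
                        num_stages = 5L, pfe_stages = 2:5,
                        dense_sizes = c(32L, 16L), num_classes = 3L,
                        input_hw = c(64L, 64L), head_mode = "softmax")
  m <- assemble_ratcapsnet(cfg, seed = 1)
  f <- ratcapsnet:::net_fwd(m, rand_map(64, 64, 3, 9), "infer")
  hw <- 64
  ch <- 8
  for (l in 1:5) {
    expect_equal(dim(f$taps[[l]]), c(hw, hw, ch))
    expect_equal(dim(f$masks[[l]]), c(hw, hw, 1))
    hw <- hw / 2
    if (l < 5) ch <- ch * 2
  }
  expect_length(f$y5_vec, 8 * 16)
  for (P in f$pfe_maps) expect_equal(dim(P)[3], 8)  # 2 * rho
  expect_length(f$probs, 3)
  expect_equal(sum(f$probs), 1, tolerance = 1e-6)
})

test_that("pyramid extractor: channel widths at every fusion level", {
  pp <- init_pfe_params(6, rho = 2, seed = 4)
  x <- rand_map(8, 8, 6, 5)
  P <- pfe_forward(pp, x)
  expect_equal(dim(P), c(8, 8, 4))  # 2 * rho, spatial preserved
  inner <- ratcapsnet:::pfe_fwd(pp, x)
  for (pr in inner$cache$pr) expect_equal(dim(pr)[3], 4)   # pairwise concat: 2*rho
  expect_equal(dim(inner$cache$cc)[3], 12)                 # 6 * rho before final fusion
  # zero parameters propagate to an identically zero output
  ppz <- ratcapsnet:::nested_zero(pp)
  expect_true(all(pfe_forward(ppz, x) == 0))
})

test_that("decision head: concat length, softmax normalization, sigmoid range", {
  cfg <- network_config()  # n = 32, rho = 16, 4 pyramid stages
  din <- 512 + 4 * 32
  hp <- ratcapsnet:::with_seed(1, ratcapsnet:::init_head(din, c(512L, 128L), 3L))
  y5 <- rnorm(512)
  ps <- lapply(1:4, function(i) rnorm(32))
  pr <- decision_forward(hp, y5, ps, head_mode = "softmax")
  expect_length(pr, 3)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_error(decision_forward(hp, y5, ps[1:2]), "length")
  hps <- ratcapsnet:::with_seed(2, ratcapsnet:::init_head(din, c(512L, 128L), 1L))
  pb <- decision_forward(hps, y5, ps, head_mode = "sigmoid_binary")
  expect_length(pb, 1)
  expect_gte(pb, 0); expect_lte(pb, 1)
})

test_that("zero-weight network outputs the uniform softmax", {
  m <- zero_params(assemble_ratcapsnet(tiny_config(), seed = 1))
  p <- forward_image(m, array(0.5, c(8, 8, 3)))
  expect_equal(p, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("parameter count: layer formulas, size invariance, default order", {
  expect_equal(sum(lengths(ratcapsnet:::with_seed(1, ratcapsnet:::init_dense(640, 512)))),
               640 * 512 + 512)  # 328192
  expect_equal(sum(lengths(ratcapsnet:::with_seed(1, ratcapsnet:::init_conv(3, 3, 3, 32)))),
               3 * 3 * 3 * 32 + 32)  # 896
  m64 <- assemble_ratcapsnet(network_config(input_hw = c(64, 64)), seed = 1)
  m256 <- assemble_ratcapsnet(network_config(input_hw = c(256, 256)), seed = 1)
  expect_identical(count_parameters(m64), count_parameters(m256))
  # documented default-configuration count (order 1e7)
  expect_equal(count_parameters(m256), 10468838)
})

test_that("whole-network backprop matches numerical gradients on a tiny config", {
  m <- assemble_ratcapsnet(tiny_config(), seed = 5)
  set.seed(42)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  yt <- 2L
  lossfun <- function(mm) -log(ratcapsnet:::net_fwd(mm, x, "infer")$probs[yt])
  f <- ratcapsnet:::net_fwd(m, x, "train")
  dl <- f$probs
  dl[yt] <- dl[yt] - 1
  g <- ratcapsnet:::net_bwd(m, f, dl)
  fp <- ratcapsnet:::flatten_params(m$params)
  fg <- ratcapsnet:::flatten_params(g)
  set.seed(9)
  for (nm in names(fp)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- sample(length(fp[[nm]]), 1)
    eps <- 1e-5
    bump <- function(dlt) {
      leaf <- get_leaf(m$params, path)
      leaf[i] <- leaf[i] + dlt
      m2 <- m
      m2$params <- set_leaf(m$params, path, leaf)
      m2
    }
    num <- (lossfun(bump(eps)) - lossfun(bump(-eps))) / (2 * eps)
    expect_equal(fg[[nm]][i], num, tolerance = 1e-3,
                 label = sprintf("analytic grad %s[%d]", nm, i))
  }
})

test_that("gradients are nonzero for every trainable weight group", {
  m <- assemble_ratcapsnet(tiny_config(), seed = 7)
  set.seed(11)
  g_tot <- NULL
  for (b in 1:2) {  # random batch of 2
    x <- array(runif(8 * 8 * 3), c(8, 8, 3))
    f <- ratcapsnet:::net_fwd(m, x, "train")
    dl <- f$probs
    dl[sample(3, 1)] <- dl[sample(3, 1)] - 1
    g <- ratcapsnet:::net_bwd(m, f, dl)
    g_tot <- if (is.null(g_tot)) g else ratcapsnet:::nested_add(g_tot, g)
  }
  fg <- ratcapsnet:::flatten_params(g_tot)
  for (nm in names(fg))
    expect_gt(max(abs(fg[[nm]])), 0, label = sprintf("grad group %s", nm))
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(input_hw = c(100, 100)), "divisible")
  expect_error(network_config(num_stages = 3L, pfe_stages = 2:5), "subset")
  expect_error(network_config(leaky_slope = 1.2), "slope")
  expect_error(network_config(num_classes = 3, head_mode = "sigmoid_binary"),
               "sigmoid_binary")
  expect_error(assemble_ratcapsnet(tiny_config(), class_names = c("a", "b")),
               "class_names")
})
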