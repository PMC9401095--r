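# Independent brute-force oracles and small fixtures used across the suite.
# The oracles re-derive each operation from its definition with plain loops,
# never touching the package's C++ path.

naive_conv <- function(x, W, b, s) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- ceiling(H / s); Wo <- ceiling(Wd / s)
  pt <- max((Ho - 1) * s + kh - H, 0) %/% 2
  pl <- max((Wo - 1) * s + kw - Wd, 0) %/% 2
  out <- array(0, c(Ho, Wo, cout))
  for (co in 1:cout) for (jo in 1:Wo) for (io in 1:Ho) {
    acc <- b[co]
    for (ci in 1:cin) for (dx in 1:kw) for (dy in 1:kh) {
      ii <- (io - 1) * s - pt + dy
      jj <- (jo - 1) * s - pl + dx
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
        acc <- acc + x[ii, jj, ci] * W[dy, dx, ci, co]
    }
    out[io, jo, co] <- acc
  }
  out
}

naive_dwconv <- function(x, W, b, s = 1) {
  C <- dim(x)[3]
  out <- NULL
  for (c in 1:C) {
    W4 <- array(W[, , c], c(dim(W)[1], dim(W)[2], 1, 1))
    o <- naive_conv(x[, , c, drop = FALSE], W4, b[c], s)
    out <- if (is.null(out)) o else array(c(out, o), c(dim(o)[1:2], c))
  }
  out
}

naive_maxpool2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in 1:d[3]) for (j in 1:(d[2] / 2)) for (i in 1:(d[1] / 2))
    out[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  out
}

naive_gap <- function(x) {
  d <- dim(x)
  out <- numeric(d[3])
  for (c in 1:d[3]) {
    s <- 0
    for (j in 1:d[2]) for (i in 1:d[1]) s <- s + x[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

naive_metrics <- function(tp, tn, fp, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  acc <- if (tp + tn + fp + fn == 0) 0 else (tp + tn) / (tp + tn + fp + fn)
  c(prec, rec, f1, acc)
}

rand_map <- function(h, w, c, seed) {
  set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}

# Minimal configuration exercising every code path (2 stages, one pyramid
# stage, 3 classes) at 8x8 input -- cheap enough for numerical gradients.
tiny_config <- function(...) {
  network_config(base_width_n = 4L, pfe_width_rho = 2L, num_stages = 2L,
                 pfe_stages = 2L, dense_sizes = c(8L, 4L), num_classes = 3L,
                 input_hw = c(8L, 8L), head_mode = "softmax", ...)
}

# Navigate/patch a nested parameter tree by dotted path (unnamed lists are
# addressed by integer position).
get_leaf <- function(p, path) {
  for (s_ in path) {
    i <- suppressWarnings(as.integer(s_))
    p <- if (!is.na(i) && is.null(names(p))) p[[i]] else p[[s_]]
  }
  p
}
set_leaf <- function(p, path, val) {
  s_ <- path[1]
  i <- suppressWarnings(as.integer(s_))
  key <- if (!is.na(i) && is.null(names(p))) i else s_
  if (length(path) == 1) p[[key]] <- val
  else p[[key]] <- set_leaf(p[[key]], path[-1], val)
  p
}

zero_params <- function(model) {
  model$params <- ratcapsnet:::nested_zero(model$params)
  model
}
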