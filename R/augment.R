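# Image augmentation operators and the class-imbalance data protocol:
# the smallest-class-referenced 80/20 split and augmentation-based
# upsampling that balances every training class to a common target count.

#' Augmentation configuration
#'
#' Parameter ranges for the seven augmentation operators: positional
#' (rotation, flipping, shearing, warping) and colour/occlusion (random
#' erasing, additive noise, blurring). Every range is `c(lo, hi)`.
#'
#' @param rotation_degrees Rotation range in degrees (default `c(-180, 180)`).
#' @param flip_axes Subset of `c("horizontal", "vertical")`.
#' @param shear_degrees Shear range in degrees (default `c(-15, 15)`).
#' @param warp_strength Peak displacement of the smooth random warp field, in
#'   pixels (default `c(1, 4)`).
#' @param erase_fraction Area-fraction range of the erased rectangle
#'   (default `c(0.02, 0.10)`, must stay within `[0, 0.5]`).
#' @param noise_sigma Additive Gaussian noise sigma range (default
#'   `c(0.01, 0.05)` on the `[0,1]` intensity scale).
#' @param blur_sigma Gaussian blur sigma range in pixels (default
#'   `c(0.5, 1.5)`).
#' @param seed Integer seed governing recipe draws.
#' @return Object of class `"augmentation_config"`.
#' @export
augmentation_config <- function(rotation_degrees = c(-180, 180),
                                flip_axes = c("horizontal", "vertical"),
                                shear_degrees = c(-15, 15),
                                warp_strength = c(1, 4),
                                erase_fraction = c(0.02, 0.10),
                                noise_sigma = c(0.01, 0.05),
                                blur_sigma = c(0.5, 1.5),
                                seed = 1L) {
  rng <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stopf("%s must be a bounded range c(lo, hi)", nm)
    as.numeric(r)
  }
  if (any(erase_fraction < 0) || any(erase_fraction > 0.5))
    stopf("erase_fraction must lie within [0, 0.5]")
  if (!all(flip_axes %in% c("horizontal", "vertical")))
    stopf("flip_axes must be a subset of horizontal/vertical")
  structure(list(
    rotation_degrees = rng(rotation_degrees, "rotation_degrees"),
    flip_axes = flip_axes,
    shear_degrees = rng(shear_degrees, "shear_degrees"),
    warp_strength = rng(warp_strength, "warp_strength"),
    erase_fraction = rng(erase_fraction, "erase_fraction"),
    noise_sigma = rng(noise_sigma, "noise_sigma"),
    blur_sigma = rng(blur_sigma, "blur_sigma"),
    seed = as.integer(seed)
  ), class = "augmentation_config")
}

AUG_OPS <- c("rotate", "flip", "shear", "warp", "erase", "additive_noise", "blur")

# -- geometric helpers ------------------------------------------------------

# Fold a continuous index into [1, n] by reflection at the borders.
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  p <- 2 * n - 2
  j <- abs((i - 1) %% p)
  ifelse(j >= n, p - j, j) + 1
}

# Bilinear sampling of an (H, W, C) image at continuous source coordinates
# (sr, sc), reflecting out-of-range coordinates at the borders.
bilinear_sample <- function(img, sr, sc) {
  d <- dim(img)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  r0r <- reflect_index(r0, d[1]); r1r <- reflect_index(r0 + 1, d[1])
  c0r <- reflect_index(c0, d[2]); c1r <- reflect_index(c0 + 1, d[2])
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    v <- m[cbind(r0r, c0r)] * (1 - fr) * (1 - fc) +
      m[cbind(r1r, c0r)] * fr * (1 - fc) +
      m[cbind(r0r, c1r)] * (1 - fr) * fc +
      m[cbind(r1r, c1r)] * fr * fc
    out[, , ch] <- v
  }
  out
}

# Target-pixel grids (row, col) for an (H, W) raster, as long vectors in
# column-major order.
grid_coords <- function(h, w) {
  list(r = rep(seq_len(h), times = w), c = rep(seq_len(w), each = h))
}

aug_rotate <- function(img, degrees) {
  if (degrees %% 360 == 0) return(img)
  d <- dim(img); g <- grid_coords(d[1], d[2])
  th <- degrees * pi / 180
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  dr <- g$r - cr; dc <- g$c - cc
  sr <- cos(th) * dr - sin(th) * dc + cr
  sc <- sin(th) * dr + cos(th) * dc + cc
  bilinear_sample(img, sr, sc)
}

aug_flip <- function(img, axis = "horizontal") {
  if (axis == "horizontal") img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

aug_shear <- function(img, degrees) {
  if (degrees == 0) return(img)
  d <- dim(img); g <- grid_coords(d[1], d[2])
  cr <- (d[1] + 1) / 2
  sc <- g$c + tan(degrees * pi / 180) * (g$r - cr)
  bilinear_sample(img, g$r, sc)
}

# Smooth random displacement field: coarse Gaussian grid bilinearly
# upsampled, peak-normalized to `strength` pixels.
aug_warp <- function(img, strength, grid = 4L) {
  d <- dim(img)
  field <- function() {
    f <- matrix(rnorm(grid * grid), grid, grid)
    up <- bilinear_resize(array(f, c(grid, grid, 1L)), d[1], d[2])[, , 1]
    if (max(abs(up)) > 0) up / max(abs(up)) * strength else up
  }
  dr <- field(); dc <- field()
  g <- grid_coords(d[1], d[2])
  bilinear_sample(img, g$r + as.vector(dr), g$c + as.vector(dc))
}

aug_erase <- function(img, fraction_range) {
  d <- dim(img)
  f <- runif(1, fraction_range[1], fraction_range[2])
  aspect <- runif(1, 0.6, 1.6)
  eh <- max(1L, min(d[1], round(sqrt(f * d[1] * d[2] * aspect))))
  ew <- max(1L, min(d[2], round(f * d[1] * d[2] / eh)))
  r0 <- sample.int(d[1] - eh + 1L, 1L)
  c0 <- sample.int(d[2] - ew + 1L, 1L)
  img[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L), ] <-
    array(runif(eh * ew * d[3]), c(eh, ew, d[3]))
  img
}

aug_noise <- function(img, sigma) {
  clip01(img + array(rnorm(length(img), sd = sigma), dim(img)))
}

aug_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(img)
  pad_r <- reflect_index(seq(1 - r, d[1] + r), d[1])
  pad_c <- reflect_index(seq(1 - r, d[2] + r), d[2])
  out <- img
  for (ch in seq_len(d[3])) {
    m <- img[pad_r, pad_c, ch]
    tmp <- matrix(0, d[1], ncol(m))
    for (i in seq_along(k)) tmp <- tmp + k[i] * m[i:(i + d[1] - 1L), ]
    res <- matrix(0, d[1], d[2])
    for (i in seq_along(k)) res <- res + k[i] * tmp[, i:(i + d[2] - 1L)]
    out[, , ch] <- res
  }
  out
}

#' Apply one augmentation operator
#'
#' Deterministic under `(params, seed)`. Geometric operators fill exposed
#' borders by reflection; `erase` replaces a random rectangle with uniform
#' noise; all operators preserve the image shape and the `[0, 1]` range.
#'
#' @param image Array `(H, W, C)` with values in `[0, 1]`.
#' @param op_name One of `"rotate"`, `"flip"`, `"shear"`, `"warp"`,
#'   `"erase"`, `"additive_noise"`, `"blur"`.
#' @param params Operator parameters: `degrees` (rotate/shear), `axis`
#'   (flip), `strength` (warp), `fraction` range (erase), `sigma`
#'   (additive_noise/blur).
#' @param seed Integer seed for the operator's internal randomness.
#' @return Augmented image, same shape and range as the input.
#' @export
augment_once <- function(image, op_name, params = list(), seed = 1L) {
  if (!op_name %in% AUG_OPS)
    stopf("unknown augmentation '%s' (expected one of %s)", op_name,
          paste(AUG_OPS, collapse = ", "))
  image <- as_feature_map(image)
  with_seed(seed, switch(op_name,
    rotate = aug_rotate(image, params$degrees %||% 0),
    flip = aug_flip(image, params$axis %||% "horizontal"),
    shear = aug_shear(image, params$degrees %||% 0),
    warp = aug_warp(image, params$strength %||% 2),
    erase = aug_erase(image, params$fraction %||% c(0.02, 0.10)),
    additive_noise = aug_noise(image, params$sigma %||% 0.02),
    blur = aug_blur(image, params$sigma %||% 1)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw a random augmentation recipe (1-2 operators with parameters sampled
# from the configured ranges). Caller wraps in with_seed.
draw_recipe <- function(cfg) {
  n_ops <- sample(1:2, 1)
  ops <- sample(AUG_OPS, n_ops)
  lapply(ops, function(op) {
    params <- switch(op,
      rotate = list(degrees = runif(1, cfg$rotation_degrees[1],
                                    cfg$rotation_degrees[2])),
      flip = list(axis = sample(cfg$flip_axes, 1)),
      shear = list(degrees = runif(1, cfg$shear_degrees[1],
                                   cfg$shear_degrees[2])),
      warp = list(strength = runif(1, cfg$warp_strength[1],
                                   cfg$warp_strength[2])),
      erase = list(fraction = cfg$erase_fraction),
      additive_noise = list(sigma = runif(1, cfg$noise_sigma[1],
                                          cfg$noise_sigma[2])),
      blur = list(sigma = runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2]))
    )
    list(op = op, params = params, seed = sample.int(2^30, 1))
  })
}

#' Apply an augmentation recipe
#'
#' @param image Array `(H, W, C)` in `[0, 1]`.
#' @param recipe List of steps as produced by [balance_upsample()], each with
#'   `op`, `params`, `seed`; `NULL` means identity.
#' @return Augmented image.
#' @export
apply_recipe <- function(image, recipe) {
  if (is.null(recipe)) return(image)
  for (step in recipe)
    image <- augment_once(image, step$op, step$params, step$seed)
  image
}

#' Smallest-class-referenced train/validation split
#'
#' The smallest class is split `ratio`/(1-`ratio`); the size of its
#' validation side, `v = round((1 - ratio) * m)`, becomes the reference: `v`
#' items are drawn uniformly without replacement from *every* class as its
#' validation set (so all validation sets have equal size), and the
#' remaining items of each class form that class's training pool.
#'
#' @param classes Named list mapping class name to a vector of image
#'   identifiers (unique within a class).
#' @param ratio Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return Object of class `"dataset_split"`: list with `train`, `val`
#'   (named lists of identifier vectors) and `seed`.
#' @export
split_by_smallest_class <- function(classes, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  if (!length(classes) || is.null(names(classes)))
    stopf("classes must be a non-empty named list")
  sizes <- vapply(classes, length, 0L)
  if (any(sizes == 0)) stopf("class '%s' is empty", names(classes)[sizes == 0][1])
  for (nm in names(classes))
    if (anyDuplicated(classes[[nm]]))
      stopf("identifiers within class '%s' must be unique", nm)
  m <- min(sizes)
  v <- round((1 - ratio) * m)
  stopifnot(v <= m)  # smallest class defines v, cannot exceed any class
  split <- with_seed(seed, {
    val <- train <- list()
    for (nm in names(classes)) {
      ids <- classes[[nm]]
      pick <- if (v > 0) sample(seq_along(ids), v) else integer()
      val[[nm]] <- ids[pick]
      train[[nm]] <- if (v > 0) ids[-pick] else ids
    }
    list(train = train, val = val)
  })
  structure(list(train = split$train, val = split$val, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> (seed", x$seed, ")\n")
  for (nm in names(x$train))
    cat(sprintf("  %-18s train %5d  val %4d\n", nm, length(x$train[[nm]]),
                length(x$val[[nm]])))
  invisible(x)
}

#' Augmentation-based upsampling to a common target count
#'
#' Returns exactly `target_count` entries for one class's training pool:
#' every original identifier once with a `NULL` (identity) recipe, plus
#' `target_count - length(pool)` entries drawing identifiers uniformly with
#' replacement, each paired with a random augmentation recipe from
#' `aug_config`. Deterministic under `aug_config$seed`.
#'
#' @param pool Non-empty vector of image identifiers.
#' @param target_count Target entries (>= `length(pool)`), default 3000.
#' @param aug_config An [augmentation_config()].
#' @return List of `target_count` entries, each `list(id, recipe)`.
#' @export
balance_upsample <- function(pool, target_count = 3000L,
                             aug_config = augmentation_config()) {
  if (!length(pool)) stopf("pool must be non-empty")
  if (target_count < length(pool))
    stopf("target_count (%d) must be >= pool size (%d)", target_count,
          length(pool))
  originals <- lapply(pool, function(id) list(id = id, recipe = NULL))
  extra_n <- target_count - length(pool)
  if (extra_n == 0) return(originals)
  extras <- with_seed(aug_config$seed, {
    ids <- pool[sample.int(length(pool), extra_n, replace = TRUE)]
    lapply(ids, function(id) list(id = id, recipe = draw_recipe(aug_config)))
  })
  c(originals, extras)
}

# Serialize one recipe as a compact JSON string for the split manifest.
recipe_to_json <- function(recipe) {
  if (is.null(recipe)) return("")
  as.character(jsonlite::toJSON(recipe, auto_unbox = TRUE, digits = 10))
}

recipe_from_json <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  jsonlite::fromJSON(s, simplifyVector = FALSE)
}
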