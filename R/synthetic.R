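# Seeded synthetic wireless-capsule-endoscopy imagery. Small RGB frames of
# textured pink-red mucosa inside a circular capsule field of view, with one
# class-specific lesion structure per abnormal class. The morphology is
# chosen for visual plausibility and small-scale separability, not clinical
# fidelity; it exists so every other module is testable without downloads.

WCE_CLASSES <- c("normal", "ulcer", "erosion", "blood", "angiectasia",
                 "lymphangiectasia")

#' Lesion specification for one synthetic class
#'
#' @param class_name One of `"normal"`, `"ulcer"`, `"erosion"`, `"blood"`,
#'   `"angiectasia"`, `"lymphangiectasia"`.
#' @return Object of class `"lesion_spec"`: list with `class_name`,
#'   `area_fraction` range (within `(0, 0.4]`), `color_mean` (RGB triplet in
#'   `[0,1]`), `color_sd`, and `shape` (`"ellipse"`, `"blob"`,
#'   `"tortuous"` or `"none"`).
#' @export
lesion_spec <- function(class_name) {
  specs <- list(
    normal = list(area_fraction = c(0, 0), color_mean = c(0, 0, 0),
                  color_sd = 0, shape = "none"),
    # large saturated-red region
    blood = list(area_fraction = c(0.10, 0.30),
                 color_mean = c(0.55, 0.05, 0.05), color_sd = 0.02,
                 shape = "blob"),
    # pale centre with red rim
    ulcer = list(area_fraction = c(0.03, 0.10),
                 color_mean = c(0.88, 0.82, 0.62), color_sd = 0.03,
                 shape = "ellipse"),
    # small pale patch
    erosion = list(area_fraction = c(0.01, 0.04),
                   color_mean = c(0.82, 0.66, 0.55), color_sd = 0.03,
                   shape = "ellipse"),
    # small bright-red tortuous mark
    angiectasia = list(area_fraction = c(0.004, 0.03),
                       color_mean = c(0.72, 0.08, 0.08), color_sd = 0.02,
                       shape = "tortuous"),
    # small white dot
    lymphangiectasia = list(area_fraction = c(0.002, 0.012),
                            color_mean = c(0.95, 0.93, 0.88), color_sd = 0.02,
                            shape = "ellipse")
  )
  if (!class_name %in% names(specs))
    stopf("unknown class '%s' (expected one of %s)", class_name,
          paste(WCE_CLASSES, collapse = ", "))
  structure(c(list(class_name = class_name), specs[[class_name]]),
            class = "lesion_spec")
}

# Low-frequency multiplicative texture: coarse Gaussian grid, bilinearly
# upsampled, centred at 1.
coarse_field <- function(h, w, grid = 6L, amp = 0.12) {
  f <- matrix(rnorm(grid * grid), grid, grid)
  up <- bilinear_resize(array(f, c(grid, grid, 1L)), h, w)[, , 1]
  1 + amp * up / max(1e-9, max(abs(up)))
}

# Soft elliptical radial field: rho <= 1 inside; Fourier boundary
# perturbation for blobs.
radial_field <- function(h, w, cr, cc, ra, rb, theta = 0, wobble = 0) {
  g <- grid_coords(h, w)
  dr <- g$r - cr; dc <- g$c - cc
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  rho <- sqrt((u / ra)^2 + (v / rb)^2)
  if (wobble > 0) {
    phi <- atan2(v, u)
    pert <- 1 + wobble * (0.6 * sin(2 * phi + runif(1, 0, 2 * pi)) +
                          0.4 * sin(3 * phi + runif(1, 0, 2 * pi)))
    rho <- rho * pert
  }
  matrix(rho, h, w)
}

blend <- function(img, color, alpha) {
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - alpha) + color[ch] * alpha
  img
}

# Distance-limited polyline mask for tortuous vascular marks.
curve_mask <- function(h, w, n_seg = 6L, step, thickness) {
  pts <- matrix(0, n_seg + 1, 2)
  pts[1, ] <- c(h / 2 + rnorm(1, 0, h / 10), w / 2 + rnorm(1, 0, w / 10))
  ang <- runif(1, 0, 2 * pi)
  for (i in seq_len(n_seg)) {
    ang <- ang + rnorm(1, 0, 0.9)
    pts[i + 1, ] <- pts[i, ] + step * c(sin(ang), cos(ang))
  }
  g <- grid_coords(h, w)
  dmin <- rep(Inf, h * w)
  for (i in seq_len(n_seg)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((g$r - a[1]) * ab[1] + (g$c - a[2]) * ab[2]) / max(len2, 1e-9)
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((g$r - (a[1] + t * ab[1]))^2 + (g$c - (a[2] + t * ab[2]))^2)
    dmin <- pmin(dmin, d)
  }
  matrix(dmin <= thickness, h, w)
}

#' Generate one synthetic WCE image
#'
#' Draws a textured pink-red mucosa background (low-frequency multiplicative
#' noise over a mucosa-tone base) under a circular vignette emulating the
#' capsule's field of view, and—for abnormal classes—one lesion per the
#' class's [lesion_spec()]. Fully deterministic under `seed`.
#'
#' @param spec A `"lesion_spec"` or a class name.
#' @param hw `c(H, W)` (default `c(64, 64)`).
#' @param seed Integer seed.
#' @return List with `image` (`(H, W, 3)` in `[0, 1]`) and `mask`
#'   (binary `(H, W)` lesion mask; all-zero for `"normal"`).
#' @export
generate_image <- function(spec, hw = c(64, 64), seed = 1L) {
  if (is.character(spec)) spec <- lesion_spec(spec)
  stopifnot(inherits(spec, "lesion_spec"))
  h <- as.integer(hw[1]); w <- as.integer(rep(hw, length.out = 2)[2])
  if (h < 8 || w < 8) stopf("hw must be at least 8x8")
  with_seed(seed, {
    base <- clip01(c(0.72, 0.42, 0.40) + rnorm(3, 0, 0.03))
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- base[ch] * coarse_field(h, w)
    # capsule field-of-view vignette
    g <- grid_coords(h, w)
    rad <- sqrt((g$r - (h + 1) / 2)^2 + (g$c - (w + 1) / 2)^2) /
      (0.52 * min(h, w))
    vig <- matrix(1 / (1 + exp((rad - 1) * 14)), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (0.12 + 0.88 * vig)
    mask <- matrix(0L, h, w)
    if (spec$shape != "none") {
      color <- clip01(spec$color_mean + rnorm(3, 0, spec$color_sd))
      # keep the lesion inside the field of view
      cr <- h / 2 + rnorm(1, 0, h / 12)
      cc <- w / 2 + rnorm(1, 0, w / 12)
      lo <- spec$area_fraction[1]; hi <- spec$area_fraction[2]
      f_target <- runif(1, lo + 0.15 * (hi - lo), hi - 0.25 * (hi - lo))
      if (spec$shape %in% c("ellipse", "blob")) {
        q <- runif(1, 0.75, 1.35)
        ra <- sqrt(f_target * h * w * q / pi)
        rb <- ra / q
        wob <- if (spec$shape == "blob") 0.12 else 0
        rho <- radial_field(h, w, cr, cc, ra, rb, runif(1, 0, pi), wob)
        inside <- rho <= 1
        alpha <- pmin(pmax((1.12 - rho) / 0.24, 0), 1)  # soft edge
        img <- blend(img, color, array(alpha, c(h, w)))
        if (spec$class_name == "ulcer") {
          rim <- pmin(pmax(1 - abs(rho - 1.18) / 0.22, 0), 1)
          img <- blend(img, c(0.62, 0.10, 0.10), array(rim, c(h, w)))
          inside <- rho <= 1.3   # rim belongs to the lesion
        }
        mask[inside] <- 1L
      } else {  # tortuous
        span <- sqrt(f_target * h * w)
        thick <- max(1, 0.22 * span)
        step <- max(2, 0.55 * span)
        cm <- curve_mask(h, w, 6L, step, thick)
        alpha <- array(0.9 * cm, c(h, w))
        img <- blend(img, color, alpha)
        mask[cm] <- 1L
      }
    }
    img <- clip01(img + array(rnorm(h * w * 3, 0, 0.01), c(h, w, 3)))
    list(image = img, mask = mask)
  })
}

#' Generate a class-imbalanced synthetic dataset on disk
#'
#' Writes `root/<class>/<class>_<i>.png` matching the layout expected by the
#' data protocol, plus a manifest CSV listing every file, its class and the
#' per-image seed. Regenerating with the same seed reproduces byte-identical
#' files.
#'
#' @param class_counts Named integer vector, e.g.
#'   `c(normal = 200, blood = 40)`; all counts >= 1.
#' @param hw `c(H, W)` per image (default `c(64, 64)`).
#' @param seed Master seed; per-image seeds are derived from it.
#' @param out_dir Destination directory (created if missing).
#' @return Invisibly, the manifest data.frame (`file`, `class`, `seed`).
#' @export
generate_dataset <- function(class_counts, hw = c(64, 64), seed = 1L,
                             out_dir) {
  if (is.null(names(class_counts)) || any(class_counts < 1))
    stopf("class_counts must be a named vector of counts >= 1")
  for (cl in names(class_counts)) lesion_spec(cl)  # validate names early
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(class_counts)) {
    cl <- names(class_counts)[ci]
    cdir <- file.path(out_dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(class_counts[ci])) {
      s <- derive_seed(seed, ci, i)
      im <- generate_image(lesion_spec(cl), hw, s)
      f <- file.path(cdir, sprintf("%s_%04d.png", cl, i))
      write_image_png(im$image, f)
      rows[[length(rows) + 1]] <- data.frame(file = f, class = cl, seed = s,
                                             stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
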