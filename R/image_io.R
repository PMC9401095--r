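# Image loading, resizing and 8-bit PNG export.

#' Bilinear image resize
#'
#' @param img Array `(H, W, C)`.
#' @param h,w Target dims.
#' @return Array `(h, w, C)`.
#' @export
bilinear_resize <- function(img, h, w) {
  img <- as_feature_map(img)
  d <- dim(img)
  if (d[1] == h && d[2] == w) return(img)
  # map target pixel centres onto source pixel centres
  sr <- (seq_len(h) - 0.5) * d[1] / h + 0.5
  sc <- (seq_len(w) - 0.5) * d[2] / w + 0.5
  out <- array(0, c(h, w, d[3]))
  g_r <- rep(sr, times = w)
  g_c <- rep(sc, each = h)
  tmp <- bilinear_sample_into(img, g_r, g_c, h, w)
  tmp
}

bilinear_sample_into <- function(img, sr, sc, h, w) {
  d <- dim(img)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  r0r <- reflect_index(r0, d[1]); r1r <- reflect_index(r0 + 1, d[1])
  c0r <- reflect_index(c0, d[2]); c1r <- reflect_index(c0 + 1, d[2])
  out <- array(0, c(h, w, d[3]))
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

#' Load an RGB image from PNG or JPEG
#'
#' Grayscale images are replicated to three channels; an alpha channel is
#' dropped. Values are returned in `[0, 1]`.
#'
#' @param path File path ending in .png/.jpg/.jpeg (case-insensitive).
#' @param hw Optional target `c(H, W)`; when given the image is bilinearly
#'   resized.
#' @return Array `(H, W, 3)`.
#' @export
load_image <- function(path, hw = NULL) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("the 'jpeg' package is required to read %s", path)
      jpeg::readJPEG(path)
    },
    stopf("unsupported image format '.%s' (%s)", ext, path))
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (!is.null(hw)) img <- bilinear_resize(img, hw[1], hw[2])
  img
}

#' Write an image as 8-bit PNG
#'
#' Values are clipped to `[0, 1]` and quantized to 8 bits. A single-channel
#' array or matrix is written as grayscale.
#'
#' @param img Matrix `(H, W)` or array `(H, W, 1|3)`.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  img <- clip01(img)
  if (dim(img)[3] == 1L) img <- img[, , 1]
  png::writePNG(img, target = path)
  invisible(path)
}
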