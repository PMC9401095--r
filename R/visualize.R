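# Attention-mask and pyramid-map visualization: per-stage masks, masked
# inputs, their contrast-stretched versions, and example channels of the
# stage-3 pyramid map.

#' Min-max contrast stretch
#'
#' Rescales to the full `[0, 1]` range; a constant (zero-dynamic-range) map
#' is rendered mid-gray.
#'
#' @param x Numeric array or matrix.
#' @return Same shape, values in `[0, 1]`.
#' @export
contrast_stretch <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(array(0.5, dim(x) %||% length(x)))
  (x - rng[1]) / diff(rng)
}

#' Visualize attention masks and pyramid maps for one image
#'
#' Writes, per encoder stage `l`: the attention mask (`mask_stage<l>.png`,
#' 8-bit grayscale), the input masked by the bilinearly upsampled mask
#' (`masked_stage<l>.png`), and its contrast-stretched rendering
#' (`masked_stage<l>_stretched.png`). Additionally writes three channels of
#' the stage-3 pyramid map (or of the first configured pyramid stage) as
#' `pfe<l>_map<j>.png`, contrast-stretched.
#'
#' @param model A `"ratcaps_model"` or checkpoint directory.
#' @param image_path Path to a PNG/JPEG image.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
visualize_attention <- function(model, image_path, out_dir) {
  if (!inherits(model, "ratcaps_model")) model <- load_checkpoint(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- load_image(image_path, model$config$input_hw)
  maps <- extract_attention_maps(model, img)
  files <- character()
  put <- function(arr, name) {
    f <- file.path(out_dir, name)
    write_image_png(arr, f)
    files <<- c(files, f)
  }
  d <- dim(img)
  for (l in seq_along(maps$masks)) {
    mask <- maps$masks[[l]]
    put(mask[, , 1], sprintf("mask_stage%d.png", l))
    up <- bilinear_resize(mask, d[1], d[2])
    masked <- img * as.vector(up)
    put(masked, sprintf("masked_stage%d.png", l))
    put(contrast_stretch(masked), sprintf("masked_stage%d_stretched.png", l))
  }
  pfe_keys <- names(maps$pfe_maps)
  if (length(pfe_keys)) {
    key <- if ("3" %in% pfe_keys) "3" else pfe_keys[1]
    P <- maps$pfe_maps[[key]]
    for (j in seq_len(min(3L, dim(P)[3])))
      put(contrast_stretch(P[, , j]), sprintf("pfe%s_map%d.png", key, j))
  }
  invisible(files)
}
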