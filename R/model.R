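# Full-network assembly: wiring of the compression pipeline (encoder chain),
# the regional-correlative pipeline (PFE over registered taps) and the
# decision head, plus whole-model forward/backward and parameter utilities.

# -- nested parameter-tree helpers (leaves are numeric arrays) --------------
nested_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nested_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

nested_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nested_map1(a[[i]], f)
    out
  } else f(a)
}

nested_add <- function(a, b) nested_map2(a, b, `+`)
nested_zero <- function(a) nested_map1(a, function(x) x * 0)

# Flatten to a named list of leaves, names like "enc.1.vam.squeeze.W".
flatten_params <- function(p, prefix = character()) {
  if (!is.list(p)) {
    out <- list(p)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  out <- list()
  for (i in seq_along(p))
    out <- c(out, flatten_params(p[[i]], c(prefix, nms[i])))
  out
}

#' Assemble the full dual-pipeline network
#'
#' Wires `num_stages` encoder stages in series (compression pipeline), routes
#' the registered pre-attention taps of `pfe_stages` through pyramid feature
#' extraction and global average pooling (regional-correlative pipeline), and
#' feeds the concatenated pooled vectors into the dense decision head. All
#' weights are trainable; the forward pass maps one RGB image to class
#' probabilities.
#'
#' @param config A [network_config()].
#' @param seed Seed governing the weight initialization.
#' @param class_names Optional character vector of length `num_classes`.
#' @return An object of class `"ratcaps_model"`.
#' @export
assemble_ratcapsnet <- function(config, seed = 1L, class_names = NULL) {
  validate_network_config(config)
  if (!is.null(class_names) && length(class_names) != config$num_classes)
    stopf("class_names must have length num_classes = %d", config$num_classes)
  S <- config$num_stages
  params <- with_seed(seed, {
    enc <- vector("list", S)
    cin <- 3L
    for (l in seq_len(S)) {
      cout <- channel_rule(cin, config$base_width_n)
      enc[[l]] <- init_encoder(cin, cout)
      cin <- cout
    }
    pfe <- list()
    for (l in config$pfe_stages)
      pfe[[as.character(l)]] <- init_pfe(stage_channels(config, l),
                                         config$pfe_width_rho)
    din <- stage_channels(config, S) +
      length(config$pfe_stages) * 2L * config$pfe_width_rho
    n_out <- if (config$head_mode == "sigmoid_binary") 1L else config$num_classes
    list(enc = enc, pfe = pfe,
         head = init_head(din, config$dense_sizes, n_out))
  })
  structure(list(config = config, params = params, seed = as.integer(seed),
                 class_names = class_names),
            class = "ratcaps_model")
}

#' @export
print.ratcaps_model <- function(x, ...) {
  cat("<ratcaps_model>\n")
  print(x$config)
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$class_names))
    cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalar weights in an assembled model. The count
#' is invariant to the configured input size (the body is all-convolutional
#' and global pooling makes the head input size-independent).
#'
#' @param model A `"ratcaps_model"`.
#' @return Integer-valued numeric.
#' @export
count_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, 0L))
}

# Whole-network forward. mode = "train" keeps every intermediate needed for
# backprop; "infer" keeps only taps, masks and pyramid maps.
net_fwd <- function(model, x, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  cfg <- model$config
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] != cfg$input_hw[1] || d[2] != cfg$input_hw[2] || d[3] != 3L)
    stopf("input must be %dx%dx3, got %dx%dx%d",
          cfg$input_hw[1], cfg$input_hw[2], d[1], d[2], d[3])
  S <- cfg$num_stages
  st <- vector("list", S)
  cur <- x
  for (l in seq_len(S)) {
    st[[l]] <- encoder_fwd(model$params$enc[[l]], cur, cfg$leaky_slope)
    cur <- st[[l]]$y
  }
  y5_vec <- global_average_pool(cur)
  pf <- list()
  p_vecs <- list()
  for (l in cfg$pfe_stages) {
    key <- as.character(l)
    pf[[key]] <- pfe_fwd(model$params$pfe[[key]], st[[l]]$x_r, cfg$leaky_slope)
    p_vecs[[key]] <- global_average_pool(pf[[key]]$P)
  }
  z <- c(y5_vec, unlist(p_vecs, use.names = FALSE))
  hd <- head_fwd(model$params$head, z, cfg$leaky_slope, cfg$head_mode)
  out <- list(probs = hd$probs, logits = hd$logits, y5_vec = y5_vec,
              p_vecs = p_vecs,
              masks = lapply(st, `[[`, "mask"),
              taps = lapply(st, `[[`, "x_r"),
              pfe_maps = lapply(pf, `[[`, "P"))
  if (mode == "train")
    out$cache <- list(st = st, pf = pf, head = hd$cache,
                      y_final_dim = dim(cur))
  out
}

# Whole-network backward from d(loss)/d(logits); returns a gradient tree
# mirroring model$params.
net_bwd <- function(model, fwd, dlogits) {
  cfg <- model$config
  cache <- fwd$cache
  S <- cfg$num_stages
  hb <- head_bwd(model$params$head, cache$head, dlogits, cfg$leaky_slope)
  cS <- stage_channels(cfg, S)
  g_y5 <- hb$gz[seq_len(cS)]
  gy <- gap_bwd(g_y5, cache$y_final_dim)
  g_xr_extra <- vector("list", S)
  off <- cS
  gp_pfe <- list()
  rho2 <- 2L * cfg$pfe_width_rho
  for (l in cfg$pfe_stages) {
    key <- as.character(l)
    g_pvec <- hb$gz[(off + 1):(off + rho2)]
    off <- off + rho2
    gP <- gap_bwd(g_pvec, dim(fwd$pfe_maps[[key]]))
    pb <- pfe_bwd(model$params$pfe[[key]], cache$pf[[key]]$cache, gP,
                  cfg$leaky_slope)
    gp_pfe[[key]] <- pb$gp
    g_xr_extra[[l]] <- pb$gx
  }
  gp_enc <- vector("list", S)
  for (l in rev(seq_len(S))) {
    eb <- encoder_bwd(model$params$enc[[l]], cache$st[[l]]$cache, gy,
                      g_xr_extra[[l]], cfg$leaky_slope)
    gp_enc[[l]] <- eb$gp
    gy <- eb$gx
  }
  list(enc = gp_enc, pfe = gp_pfe, head = hb$gp)
}

#' Run the network on one image
#'
#' @param model A `"ratcaps_model"`.
#' @param image Array `(H, W, 3)` matching the configured input size, values
#'   on any finite scale (typically `[0, 1]`).
#' @return Numeric vector of class probabilities (named when the model
#'   carries class names).
#' @export
forward_image <- function(model, image) {
  p <- net_fwd(model, image, "infer")$probs
  if (!is.null(model$class_names) && length(p) == length(model$class_names))
    names(p) <- model$class_names
  p
}

#' Extract attention masks and pyramid maps for one image
#'
#' Evaluates the network on `image` and returns the attention mask of every
#' encoder stage (each an `(H_l, W_l, 1)` array with entries in `[0, 1]`,
#' spatial dims halving per stage) and the pyramid feature map `P_l`
#' (`2*rho` channels) of every pyramid stage.
#'
#' @param model A `"ratcaps_model"`.
#' @param image Array `(H, W, 3)` matching the configured input size.
#' @return List with `masks` (list over stages `1..num_stages`) and
#'   `pfe_maps` (named list over `pfe_stages`).
#' @export
extract_attention_maps <- function(model, image) {
  f <- net_fwd(model, image, "infer")
  list(masks = f$masks, pfe_maps = f$pfe_maps)
}
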