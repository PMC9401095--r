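# Training and evaluation: cross-entropy losses, Adam, the epoch loop with
# smallest-class split + balanced augmentation, checkpointing on best
# validation loss, and evaluation against a saved checkpoint.

# -- losses -----------------------------------------------------------------
# Returns list(loss, dlogits) for one sample. `target` is the 1-based class
# index; sigmoid_binary treats class 2 as the positive class.
loss_and_grad <- function(probs, target, head_mode) {
  eps <- 1e-12
  if (head_mode == "sigmoid_binary") {
    y <- as.numeric(target == 2L)
    p <- probs[1]
    list(loss = -(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
         dlogits = p - y)
  } else {
    onehot <- numeric(length(probs))
    onehot[target] <- 1
    list(loss = -log(probs[target] + eps), dlogits = probs - onehot)
  }
}

predicted_class <- function(probs, head_mode) {
  if (head_mode == "sigmoid_binary") if (probs[1] >= 0.5) 2L else 1L
  else which.max(probs)
}

# -- Adam -------------------------------------------------------------------
adam_init <- function(params)
  list(m = nested_zero(params), v = nested_zero(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- nested_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nested_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  upd <- nested_map2(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = nested_map2(params, upd, `-`), state = state)
}

# -- dataset indexing -------------------------------------------------------

#' Index a class-per-directory image dataset
#'
#' @param root Directory containing one sub-directory per class with
#'   PNG/JPEG files.
#' @return Named list mapping class name to relative file identifiers.
#' @export
index_image_dir <- function(root) {
  if (!dir.exists(root)) stopf("data root '%s' does not exist", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (!length(dirs)) stopf("no class directories under '%s'", root)
  classes <- list()
  for (d in sort(dirs)) {
    files <- list.files(file.path(root, d), pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE)
    if (!length(files)) stopf("class directory '%s' contains no images", d)
    classes[[d]] <- file.path(d, files)
  }
  classes
}

# One forward/backward accumulation over a mini-batch of (image, target)
# pairs; returns mean loss, gradient tree and per-item predictions.
batch_grads <- function(model, xs, targets) {
  hm <- model$config$head_mode
  n <- length(xs)
  g_tot <- NULL
  loss <- 0
  preds <- integer(n)
  for (i in seq_len(n)) {
    f <- net_fwd(model, xs[[i]], "train")
    lg <- loss_and_grad(f$probs, targets[i], hm)
    loss <- loss + lg$loss
    preds[i] <- predicted_class(f$probs, hm)
    g <- net_bwd(model, f, lg$dlogits / n)
    g_tot <- if (is.null(g_tot)) g else nested_add(g_tot, g)
  }
  list(loss = loss / n, grads = g_tot, preds = preds)
}

# Forward-only loss/accuracy over a list of images.
eval_items <- function(model, xs, targets) {
  hm <- model$config$head_mode
  loss <- 0
  preds <- integer(length(xs))
  for (i in seq_along(xs)) {
    p <- net_fwd(model, xs[[i]], "infer")$probs
    loss <- loss + loss_and_grad(p, targets[i], hm)$loss
    preds[i] <- predicted_class(p, hm)
  }
  list(loss = loss / max(1, length(xs)),
       acc = mean(preds == targets), preds = preds)
}

# -- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes `model.rds` (weights) plus a self-describing `config.yaml`
#' (architecture + class names) into `dir`.
#'
#' @param model A `"ratcaps_model"`.
#' @param dir Checkpoint directory (created if missing).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  desc <- c(unclass(model$config),
            list(class_names = model$class_names, seed = model$seed))
  writeLines(yaml::as.yaml(desc), file.path(dir, "config.yaml"), sep = "")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return A `"ratcaps_model"`.
#' @export
load_checkpoint <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stopf("no checkpoint at '%s'", dir)
  readRDS(f)
}

# -- training ---------------------------------------------------------------

load_split_images <- function(root, ids, hw) {
  imgs <- vector("list", length(ids))
  names(imgs) <- ids
  for (id in ids) imgs[[id]] <- load_image(file.path(root, id), hw)
  imgs
}

#' Train the network on a class-per-directory dataset
#'
#' Executes the full protocol: smallest-class-referenced split, per-class
#' augmentation-based upsampling to `balance_target`, mini-batch Adam on the
#' softmax/sigmoid cross-entropy, per-epoch validation, early stopping on
#' validation loss and checkpointing of the best model. All randomness
#' derives from `run$seed`.
#'
#' @param run A [run_config()] with `data_root` and `out_dir` set.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (per-epoch
#'   data.frame), `split`, and `out_dir`.
#' @export
train_network <- function(run, verbose = TRUE) {
  stopifnot(inherits(run, "run_config"))
  if (is.null(run$data_root) || is.null(run$out_dir))
    stopf("run$data_root and run$out_dir must be set")
  dir.create(run$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "[%H:%M:%S] "), msg, "\n", sep = "",
        file = file.path(run$out_dir, "log.txt"), append = TRUE)
    if (verbose) message(msg)
  }

  classes <- index_image_dir(run$data_root)
  class_names <- names(classes)
  ncls <- length(class_names)
  net_cfg <- run$network
  if (net_cfg$num_classes != ncls) {
    net_cfg$num_classes <- as.integer(ncls)
    net_cfg$head_mode <- if (ncls == 2L) "sigmoid_binary" else "softmax"
    validate_network_config(net_cfg)
  }

  split <- split_by_smallest_class(classes, run$split_ratio,
                                   derive_seed(run$seed, 1))
  entries <- list()
  for (ci in seq_len(ncls)) {
    cl <- class_names[ci]
    aug <- run$augment
    aug$seed <- derive_seed(run$seed, 2, ci)
    ent <- balance_upsample(split$train[[cl]], run$balance_target, aug)
    for (e in ent)
      entries[[length(entries) + 1]] <-
        list(id = e$id, class_idx = ci, recipe = e$recipe)
  }

  # split manifest: every train entry (with recipe) and every val item
  man <- data.frame(
    identifier = c(vapply(entries, `[[`, "", "id"),
                   unlist(split$val, use.names = FALSE)),
    class = c(class_names[vapply(entries, `[[`, 0L, "class_idx")],
              rep(class_names, vapply(split$val, length, 0L))),
    partition = c(rep("train", length(entries)),
                  rep("val", sum(vapply(split$val, length, 0L)))),
    recipe = c(vapply(entries, function(e) recipe_to_json(e$recipe), ""),
               rep("", sum(vapply(split$val, length, 0L)))),
    stringsAsFactors = FALSE)
  write.csv(man, file.path(run$out_dir, "split_manifest.csv"),
            row.names = FALSE)

  hw <- net_cfg$input_hw
  all_ids <- unique(c(unlist(split$train, use.names = FALSE),
                      unlist(split$val, use.names = FALSE)))
  logf("loading %d original images at %dx%d", length(all_ids), hw[1], hw[2])
  originals <- load_split_images(run$data_root, all_ids, hw)

  val_ids <- unlist(split$val, use.names = FALSE)
  val_targets <- rep(seq_len(ncls), vapply(split$val, length, 0L))
  val_xs <- originals[val_ids]

  model <- assemble_ratcapsnet(net_cfg, seed = derive_seed(run$seed, 3),
                               class_names = class_names)
  logf("model assembled: %d stages, %s trainable parameters",
       net_cfg$num_stages, format(count_parameters(model), big.mark = ","))

  state <- adam_init(model$params)
  n_train <- length(entries)
  history <- list()
  best_val <- Inf
  best_params <- model$params
  stall <- 0L
  for (epoch in seq_len(run$max_epochs)) {
    ord <- with_seed(derive_seed(run$seed, 4, epoch),
                     sample.int(n_train, n_train))
    ep_loss <- 0
    ep_hit <- 0L
    nb <- 0L
    for (b0 in seq(1, n_train, by = run$batch_size)) {
      idx <- ord[b0:min(n_train, b0 + run$batch_size - 1L)]
      xs <- lapply(entries[idx], function(e)
        apply_recipe(originals[[e$id]], e$recipe))
      tg <- vapply(entries[idx], `[[`, 0L, "class_idx")
      bg <- batch_grads(model, xs, tg)
      st <- adam_step(model$params, bg$grads, state, run$learning_rate)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + bg$loss * length(idx)
      ep_hit <- ep_hit + sum(bg$preds == tg)
      nb <- nb + 1L
    }
    tr_loss <- ep_loss / n_train
    tr_acc <- ep_hit / n_train
    va <- eval_items(model, val_xs, val_targets)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                   train_acc = tr_acc, val_loss = va$loss,
                                   val_acc = va$acc)
    logf("epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
         epoch, tr_loss, tr_acc, va$loss, va$acc)
    if (length(val_xs) == 0 || va$loss < best_val - 1e-6) {
      best_val <- va$loss
      best_params <- model$params
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= run$patience) {
      logf("early stop at epoch %d (patience %d)", epoch, run$patience)
      break
    }
    if (!is.null(run$stop_train_acc) && tr_acc >= run$stop_train_acc) {
      logf("training-accuracy target %.2f reached at epoch %d",
           run$stop_train_acc, epoch)
      break
    }
  }
  model$params <- best_params
  hist_df <- do.call(rbind, history)
  write.csv(hist_df, file.path(run$out_dir, "history.csv"), row.names = FALSE)
  ckpt <- file.path(run$out_dir, "checkpoint")
  save_checkpoint(model, ckpt)
  write_run_config(run, file.path(run$out_dir, "run_config.yaml"))
  list(model = model, history = hist_df, split = split, out_dir = run$out_dir)
}

#' Evaluate a checkpoint on a data partition
#'
#' Re-reads the split manifest stored next to the checkpoint, runs forward
#' passes over the chosen partition (originals only, no augmentation),
#' reduces with argmax (or the 0.5 sigmoid threshold) and delegates to the
#' metrics module.
#'
#' @param checkpoint Checkpoint directory (or a `"ratcaps_model"` plus
#'   `manifest`/`data_root` given explicitly).
#' @param data_root Dataset root used in training.
#' @param partition `"val"` or `"train"`.
#' @return List with `metrics` (per-class + macro data.frame), `confusion`
#'   (matrix), `predictions` (data.frame of identifier, truth, predicted).
#' @export
evaluate_checkpoint <- function(checkpoint, data_root,
                                partition = c("val", "train")) {
  partition <- match.arg(partition)
  model <- if (inherits(checkpoint, "ratcaps_model")) checkpoint
  else load_checkpoint(checkpoint)
  man_path <- if (is.character(checkpoint))
    file.path(dirname(checkpoint), "split_manifest.csv") else NULL
  if (is.null(man_path) || !file.exists(man_path))
    stopf("split manifest not found next to checkpoint; pass the out_dir checkpoint")
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  man <- man[man$partition == partition & !nzchar(man$recipe), , drop = FALSE]
  man <- man[!duplicated(man$identifier), , drop = FALSE]
  cls <- model$class_names
  if (!all(man$class %in% cls))
    stopf("class set mismatch between checkpoint (%s) and manifest",
          paste(cls, collapse = ","))
  hw <- model$config$input_hw
  preds <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- load_image(file.path(data_root, man$identifier[i]), hw)
    p <- net_fwd(model, img, "infer")$probs
    preds[i] <- cls[predicted_class(p, model$config$head_mode)]
  }
  list(metrics = evaluate_predictions(man$class, preds, cls),
       confusion = confusion_matrix(man$class, preds, cls),
       predictions = data.frame(identifier = man$identifier,
                                truth = man$class, predicted = preds,
                                stringsAsFactors = FALSE))
}

#' Classify one image
#'
#' @param model A `"ratcaps_model"` or checkpoint directory.
#' @param image_path Path to a PNG/JPEG image (resized to the model input).
#' @return Named probability vector.
#' @export
predict_image <- function(model, image_path) {
  if (!inherits(model, "ratcaps_model")) model <- load_checkpoint(model)
  img <- load_image(image_path, model$config$input_hw)
  p <- net_fwd(model, img, "infer")$probs
  cls <- model$class_names
  if (model$config$head_mode == "sigmoid_binary" && !is.null(cls)) {
    p <- c(1 - p[1], p[1])
    names(p) <- cls
  } else if (!is.null(cls) && length(p) == length(cls)) names(p) <- cls
  p
}
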