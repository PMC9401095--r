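# Run-level configuration: everything a training run needs, serializable
# to YAML or JSON so a checkpoint is self-describing.

#' Training-run configuration
#'
#' @param data_root Directory with one sub-directory of images per class.
#' @param out_dir Output directory for checkpoints, logs and manifests.
#' @param network A [network_config()] (or a plain list of its fields).
#' @param augment An [augmentation_config()] (or a plain list of its fields).
#' @param split_ratio Training fraction of the smallest-class-referenced
#'   split (default 0.8).
#' @param balance_target Per-class training count after augmentation-based
#'   upsampling (default 3000).
#' @param loss `"auto"` (cross-entropy matching the head), `"categorical_crossentropy"`
#'   or `"binary_crossentropy"`.
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param stop_train_acc Optional training-accuracy threshold; when reached
#'   at the end of an epoch, training stops (useful for short smoke runs).
#' @param seed Master seed; every source of randomness in the run derives
#'   from it.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(data_root = NULL, out_dir = NULL,
                       network = network_config(),
                       augment = augmentation_config(),
                       split_ratio = 0.8, balance_target = 3000L,
                       loss = "auto", optimizer = "adam",
                       learning_rate = 1e-4, batch_size = 32L,
                       max_epochs = 100L, patience = 10L,
                       stop_train_acc = NULL, seed = 1L) {
  if (is.list(network) && !inherits(network, "network_config"))
    network <- do.call(network_config, network)
  if (is.list(augment) && !inherits(augment, "augmentation_config"))
    augment <- do.call(augmentation_config, augment)
  if (split_ratio <= 0 || split_ratio >= 1) stopf("split_ratio must be in (0,1)")
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  if (optimizer != "adam") stopf("only the 'adam' optimizer is implemented")
  if (!loss %in% c("auto", "categorical_crossentropy", "binary_crossentropy"))
    stopf("unknown loss '%s'", loss)
  structure(list(
    data_root = data_root, out_dir = out_dir, network = network,
    augment = augment, split_ratio = as.numeric(split_ratio),
    balance_target = as.integer(balance_target), loss = loss,
    optimizer = optimizer, learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    stop_train_acc = if (is.null(stop_train_acc)) NULL
                     else as.numeric(stop_train_acc),
    seed = as.integer(seed)
  ), class = "run_config")
}

run_config_to_list <- function(run) {
  net <- unclass(run$network)
  aug <- unclass(run$augment)
  list(data_root = run$data_root, out_dir = run$out_dir, network = net,
       augment = aug, split_ratio = run$split_ratio,
       balance_target = run$balance_target, loss = run$loss,
       optimizer = run$optimizer, learning_rate = run$learning_rate,
       batch_size = run$batch_size, max_epochs = run$max_epochs,
       patience = run$patience, stop_train_acc = run$stop_train_acc,
       seed = run$seed)
}

#' Write a run configuration to YAML or JSON
#'
#' @param run A [run_config()].
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @export
write_run_config <- function(run, path) {
  lst <- run_config_to_list(run)
  ext <- tolower(tools::file_ext(path))
  txt <- if (ext %in% c("yaml", "yml")) yaml::as.yaml(lst)
  else if (ext == "json")
    as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, null = "null"))
  else stopf("config path must end in .yaml/.yml/.json")
  txt <- sub("\n?$", "\n", txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File written by [write_run_config()] (or hand-authored with
#'   the same keys).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::yaml.load_file(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stopf("config path must end in .yaml/.yml/.json")
  lst$network <- as_plain_list(lst$network)
  lst$augment <- as_plain_list(lst$augment)
  do.call(run_config, lst)
}

as_plain_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(as.list(x), function(v) if (is.list(v)) unlist(v) else v)
}
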