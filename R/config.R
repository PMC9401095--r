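#' Network architecture configuration
#'
#' Collects every architecture hyperparameter of the dual-pipeline network in
#' one validated record: the encoder base width `n` (channels produced by
#' stage 1; doubled at every later stage), the pyramid-extractor width `rho`,
#' the number of encoder stages, the set of stages whose pre-attention taps
#' feed the regional-correlative pipeline, the two dense-layer sizes of the
#' decision head, and the classifier head mode.
#'
#' @param base_width_n Channels out of encoder stage 1 (default 32). Later
#'   stages double: 32, 64, 128, 256, 512.
#' @param pfe_width_rho Channel width of each parallel pyramid convolution
#'   (default 16); every pyramid block outputs `2*rho` channels.
#' @param num_stages Number of encoder stages (default 5).
#' @param pfe_stages Integer vector of stage indices whose taps are routed
#'   through pyramid feature extraction (default `2:5`); must lie in
#'   `2..num_stages`.
#' @param dense_sizes Two dense-layer widths of the decision head,
#'   default `c(512, 128)`.
#' @param num_classes Number of classes (>= 2).
#' @param input_hw Input height/width, each divisible by `2^num_stages`
#'   (default `c(256, 256)`), so pooling and the transposed-convolution
#'   doubling are exact at every stage.
#' @param leaky_slope Negative slope of the LeakyReLU activation (default 0.1).
#' @param head_mode `"softmax"` or `"sigmoid_binary"` (single sigmoid unit,
#'   only valid for two classes). `"auto"` picks sigmoid for 2 classes.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(base_width_n = 32L, pfe_width_rho = 16L,
                           num_stages = 5L, pfe_stages = 2:5,
                           dense_sizes = c(512L, 128L), num_classes = 2L,
                           input_hw = c(256L, 256L), leaky_slope = 0.1,
                           head_mode = c("auto", "softmax", "sigmoid_binary")) {
  head_mode <- match.arg(head_mode)
  if (head_mode == "auto")
    head_mode <- if (num_classes == 2L) "sigmoid_binary" else "softmax"
  cfg <- structure(list(
    base_width_n = as.integer(base_width_n),
    pfe_width_rho = as.integer(pfe_width_rho),
    num_stages = as.integer(num_stages),
    pfe_stages = sort(as.integer(pfe_stages)),
    dense_sizes = as.integer(dense_sizes),
    num_classes = as.integer(num_classes),
    input_hw = as.integer(rep(input_hw, length.out = 2)),
    leaky_slope = as.numeric(leaky_slope),
    head_mode = head_mode
  ), class = "network_config")
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (!is_count(cfg$base_width_n)) stopf("base_width_n must be a positive integer")
  if (cfg$base_width_n %% 2 != 0)
    stopf("base_width_n must be even (the attention squeeze halves channels)")
  if (!is_count(cfg$pfe_width_rho)) stopf("pfe_width_rho must be a positive integer")
  if (!is_count(cfg$num_stages)) stopf("num_stages must be a positive integer")
  if (length(cfg$dense_sizes) != 2 || !all(cfg$dense_sizes >= 1))
    stopf("dense_sizes must be two positive integers")
  if (!is_count(cfg$num_classes) || cfg$num_classes < 2)
    stopf("num_classes must be an integer >= 2")
  div <- 2L^cfg$num_stages
  if (any(cfg$input_hw %% div != 0))
    stopf("input_hw (%d, %d) must be divisible by 2^num_stages = %d",
          cfg$input_hw[1], cfg$input_hw[2], div)
  if (length(cfg$pfe_stages) &&
      (min(cfg$pfe_stages) < 2 || max(cfg$pfe_stages) > cfg$num_stages))
    stopf("pfe_stages must be a subset of 2..num_stages")
  if (anyDuplicated(cfg$pfe_stages)) stopf("pfe_stages must be distinct")
  if (cfg$leaky_slope <= 0 || cfg$leaky_slope >= 1)
    stopf("leaky_slope must lie in (0, 1)")
  if (cfg$head_mode == "sigmoid_binary" && cfg$num_classes != 2)
    stopf("head_mode 'sigmoid_binary' requires num_classes = 2")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>\n")
  cat(sprintf("  input %dx%d, %d stages (width n=%d), PFE on {%s} (rho=%d)\n",
              x$input_hw[1], x$input_hw[2], x$num_stages, x$base_width_n,
              paste(x$pfe_stages, collapse = ","), x$pfe_width_rho))
  cat(sprintf("  head: dense(%d, %d) -> %d classes [%s], LeakyReLU slope %.2f\n",
              x$dense_sizes[1], x$dense_sizes[2], x$num_classes, x$head_mode,
              x$leaky_slope))
  invisible(x)
}

#' Channel-width rule of the encoder chain
#'
#' An encoder stage fed with the 3-channel RGB image produces `n` channels;
#' every later stage doubles the incoming channel count.
#'
#' @param c_in Incoming channel count (>= 1).
#' @param n Base width assigned when `c_in == 3` (default 32).
#' @return The stage's output channel count.
#' @examples
#' channel_rule(3)    # 32
#' channel_rule(32)   # 64
#' @export
channel_rule <- function(c_in, n = 32L) {
  if (!is_count(c_in)) stopf("c_in must be a positive integer")
  if (c_in == 3L) as.integer(n) else 2L * as.integer(c_in)
}

# Channel count produced by stage l under a config.
stage_channels <- function(cfg, l) {
  c_out <- cfg$base_width_n
  if (l > 1) c_out <- c_out * 2L^(l - 1L)
  as.integer(c_out)
}
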