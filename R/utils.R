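#' @useDynLib ratcapsnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @importFrom utils read.csv write.csv
NULL

# Run code under a temporary RNG state; the global .Random.seed is restored
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a well-spread 31-bit child seed from (seed, stream ids).
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 1
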