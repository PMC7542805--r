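#' @importFrom stats rnorm runif rexp qnorm pnorm quantile sd var median
#'   rbinom rgamma setNames aggregate fft bw.nrd0 pt acf rweibull
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

MERSENNE <- 2147483647  # 2^31 - 1

#' Stable integer hash of a character string
#'
#' Polynomial rolling hash modulo 2^31 - 1, used to derive reproducible
#' random substreams from identifiers (e.g. individual ids) independently
#' of iteration order.
#'
#' @param x character vector.
#' @return integer vector of hashes in `[0, 2^31 - 2]`.
#' @export
hash_id <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% MERSENNE
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a substream seed from a global seed and labels
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return a single integer seed below 2^31.
#' @export
substream_seed <- function(seed, ...) {
  labs <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  as.integer((as.numeric(seed) %% MERSENNE * 48271 + hash_id(labs)) %% MERSENNE)
}

# run expr under a seed without disturbing the caller's RNG state
with_substream <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

stop_cfg <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop_cfg("`%s` must be a single positive number", name)
  invisible(x)
}
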