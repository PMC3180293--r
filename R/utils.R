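#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages draw their own stream seed from one master seed so a
#' whole run is reproducible while units/trials stay independent. The mix is a
#' small multiplicative hash of the key string, kept below 2^31.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream (e.g. `"unit_3"`).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (cc in utf8ToInt(key)) {
    h <- (h * 131 + cc) %% m
  }
  as.integer(h)
}

#' Evaluate code with a local RNG seed
#'
#' Wrapper around [withr::with_seed()] so package functions that accept a
#' `seed` argument never disturb the caller's RNG state. `seed = NULL` runs in
#' the ambient stream.
#'
#' @param seed integer or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
local_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Count events in the half-open interval [a, b). The half-open convention is
# used everywhere in the package so a spike exactly at a boundary belongs to
# exactly one epoch.
count_in <- function(x, a, b) sum(x >= a & x < b)

`%||%` <- function(x, y) if (is.null(x)) y else x
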