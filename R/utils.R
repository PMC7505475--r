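#' @useDynLib lifnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rpois integrate lm nls coef sd
NULL

# Derive a child RNG seed (< 2^31) from a base seed and a string label, so
# that independent randomness streams (wiring, initial conditions, external
# drive, solver starts, ...) never collide across protocol steps.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(salt))) h <- (h * 131 + ch) %% 1048573
  as.integer((abs(seed) * 48271 + h * 7919 + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_undefined <- function(msg) {
  cond <- structure(class = c("lifnet_undefined", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
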