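## Internal helpers shared across modules.

#' @keywords internal
#' @useDynLib pedpower, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Draw from an inverse-gamma distribution
#'
#' Shape/rate parameterization: if `x ~ InvGamma(shape, rate)` then
#' `1/x ~ Gamma(shape, rate)`.  For shape = rate = 0.5 the shape/scale and
#' shape/rate conventions coincide.
#' @noRd
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

#' Derive a per-task seed from a master seed.
#'
#' Deterministic mixing of up to three non-negative integers into a single
#' seed below 2^31, so that replicates are reproducible independently of
#' execution order.  Uses splitmix-style multiplicative hashing on doubles
#' (exact for these magnitudes).
#' @noRd
mix_seed <- function(master, a = 0L, b = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(a) * 16807 + 1) %% m
  x <- (x * 69621 + as.numeric(b) * 65539 + 1) %% m
  as.integer(x)
}

#' Run an expression with a local RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Log a message to stderr with a level prefix.
#' @noRd
pp_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
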