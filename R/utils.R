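`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never perturbs user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Digest of an arbitrary R object
#'
#' Stable content hash used for anti-leakage assertions: fitted objects
#' (n-gram inventories, idf tables, scalers, embeddings) are digested before
#' and after held-out data passes through them, and the digests must match.
#'
#' @param x any R object.
#' @return a character scalar (xxhash64 hex digest).
#' @export
object_digest <- function(x) {
  digest::digest(x, algo = "xxhash64")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## round half away from zero (base R round() rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)
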