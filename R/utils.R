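# Internal helpers shared across modules.

#' @importFrom stats coef dnbinom kmeans lm median optimize optim p.adjust
#'   pchisq prcomp qnorm quantile rbeta rbinom rchisq rnbinom rnorm rpois
#'   runif sd setNames t.test var rbinom plogis qlogis
NULL

# log(sum(exp(x))) along a vector, numerically safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp for a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  fin <- is.finite(m)
  out <- m
  out[fin] <- m[fin] + log(rowSums(exp(x[fin, , drop = FALSE] - m[fin])))
  out
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483647L)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
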