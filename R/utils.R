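#' @importFrom rlang %||%
#' @importFrom stats rnorm runif rbinom median quantile sd cor dist var setNames
#' @importFrom utils head modifyList
NULL

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label; stays < 2^31.
derive_seed <- function(seed, stream) {
  h <- rlang::hash(list(as.integer(seed), as.character(stream)))
  # fold the first 7 hex digits into a positive 32-bit integer
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483587L) + 1L
}

stop_spathgt <- function(...) stop(..., call. = FALSE)

# deterministic stable hash of an R object (key order independent for lists)
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  rlang::hash(canon(x))
}
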