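#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish failure modes programmatically.
pd_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pentadyn_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run an expression under a fixed RNG state without disturbing the caller's
## stream: every stochastic routine in the package funnels through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) pd_stop("cannot normalize a near-zero 3-vector", "geometry_error")
  v / n
}

## FNV-1a over a character scalar; used for config provenance hashes.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit modular multiply split into 16-bit halves to stay within
    ## double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
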