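#' @keywords internal
"_PACKAGE"

## NULL default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_pos <- function(x, name) {
  stop_if(!is_scalar_num(x) || x <= 0, sprintf("'%s' must be a positive finite number", name))
  invisible(x)
}

## FNV-1a 32-bit hash of a character string, reduced below 2^31.
## Used to derive per-sample RNG streams from a master seed so that adding
## or removing samples never perturbs the streams of the others.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    ## xor the low byte (h may exceed the 32-bit signed range bitwXor allows)
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    ## 32-bit modular multiply via 16-bit split to stay within double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  h %% 2147483647
}

derive_seed <- function(master_seed, key) {
  as.integer((as.numeric(master_seed) + fnv1a32(key)) %% 2147483647)
}

## Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
## state is restored afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
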