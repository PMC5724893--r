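# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable key for a variant or site.
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Pipeline-wide logger: message() so callers can suppress.
pipe_log <- function(...) message("[rvburden] ", sprintf(...))

stop_rv <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_rv(...)
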