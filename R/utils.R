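# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subject substream seed, kept inside 32-bit integer range.
derive_seed <- function(master, k) {
  m <- 2147483647
  s <- ((as.double(master) %% m) * 48271 + as.double(k) * 69621) %% m
  as.integer(s)
}

# Nearest odd window length in samples for a duration in ms (>= 3).
odd_window <- function(ms, fs) {
  k <- max(3L, as.integer(round(ms / 1000 * fs)))
  if (k %% 2L == 0L) k + 1L else k
}

# Clip numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Coerce a scalar or function-of-time to a function of time.
as_trajectory <- function(x, name) {
  if (is.function(x)) return(x)
  if (is_scalar_num(x)) return(function(t) rep(x, length(t)))
  stopf("%s must be a single number or a function of time", name)
}
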