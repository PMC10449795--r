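# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_in <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is_scalar_num(x) || x < lo || x > hi) {
    stopf("`%s` must be a single number in [%s, %s]", name, format(lo), format(hi))
  }
  invisible(x)
}

# Number of channels of an in-memory frame (matrix or H x W x 3 array).
frame_channels <- function(frame) {
  if (is.matrix(frame)) return(1L)
  if (is.array(frame) && length(dim(frame)) == 3L) return(dim(frame)[3L])
  stopf("frame must be a matrix or a 3-d array")
}
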