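# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed derived from a master seed and integer keys.
# Kept strictly below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(master, ...) {
  keys <- c(...)
  s <- as.double(master) %% 2147483629
  for (k in keys) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(s)
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_matrix_binary <- function(px) {
  if (!is.matrix(px) || length(px) == 0L) {
    stop_domain("expected a non-empty matrix of pixels")
  }
  if (!all(px %in% c(0, 1))) {
    stop_domain("binary image pixels must all be 0 or 1")
  }
  invisible(px)
}
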