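# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps every stochastic operation reproducible
# without clobbering the user's RNG stream.
with_local_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream of independent sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Robust z-score: deviations from the median scaled by 1.4826 * MAD.
robust_z <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, center = med, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    s <- stats::sd(x, na.rm = TRUE)
  }
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - med) / s
}

# Sliding-window minimum / maximum with replicated edge padding, used by the
# morphological filter. `w` is the full window width in samples.
running_extreme <- function(x, w, fun = pmin) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], w - 1L - h))
  do.call(fun, lapply(seq_len(w), function(k) xp[k:(k + n - 1L)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
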