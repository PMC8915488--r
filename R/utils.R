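# internal helpers shared across modules

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of their config
with_seed <- function(seed, code) {
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

# unscaled median absolute deviation (no 1.4826 consistency factor); the
# robust-z convention here treats MAD as the raw median of |x - median(x)|
mad_raw <- function(x, na.rm = FALSE) {
  stats::mad(x, constant = 1, na.rm = na.rm)
}

# one-tailed upper-tail standard-normal threshold for significance level alpha
z_threshold <- function(alpha) stats::qnorm(1 - alpha)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
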