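# Internal helpers: argument checking and seed plumbing.

stop_bad_arg <- function(msg) rlang::abort(msg, class = "vtburden_error")

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_bad_arg(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x == round(x)) &&
    all(x >= if (positive) 1 else 0)
  if (!ok) {
    stop_bad_arg(sprintf(
      "`%s` must be %s integer(s)", name,
      if (positive) "positive" else "non-negative"
    ))
  }
  invisible(x)
}

# Single root seed; per-component child seeds at fixed offsets so that adding
# a new consumer of randomness never perturbs the streams of existing ones.
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

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
  set.seed(seed)
  force(code)
}
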