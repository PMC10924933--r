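# internal helpers -----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_param("`%s` must be a single number", name)
  }
  if (x < lower || x > upper) {
    stop_param("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_simplex <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < -tol)) {
    stop_param("`%s` must be a vector of non-negative probabilities", name)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop_param("`%s` must sum to 1 (got %.8f)", name, sum(p))
  }
  invisible(p)
}

# All generators and Monte-Carlo routines funnel their seed through here so a
# single integer reproduces a call byte-for-byte; NULL leaves the caller's
# RNG stream untouched.
seed_rng <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  check_scalar_number(seed, "seed")
  set.seed(as.integer(seed))
  invisible(NULL)
}
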