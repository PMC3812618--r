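# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# (parameters, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_finite <- function(x, what = "samples") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

is_monotone <- function(x) {
  d <- diff(x)
  all(d >= 0) || all(d <= 0)
}

#' Count zero crossings of a sequence
#'
#' Sign changes between consecutive non-zero samples; samples exactly equal
#' to zero are ignored so that a tangency does not count twice.
#'
#' @param x numeric vector.
#' @return integer count.
#' @keywords internal
#' @noRd
n_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

signal_energy <- function(x) sum(x^2)

trapz <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * sum((y[-1] + y[-n]) / 2)
}

# Cumulative trapezoidal integral, same length as input, starting at 0.
cumtrapz <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(dx * (y[-1] + y[-n]) / 2))
}
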