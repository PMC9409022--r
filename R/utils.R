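# Internal helpers shared across modules: argument checking, seeded RNG
# streams, quadrature and interpolation on wavelength/time grids.

stop_tf <- function(...) stop(..., call. = FALSE)

check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_tf(msg)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_strictly_increasing <- function(x, what = "grid") {
  check_that(is.numeric(x) && length(x) >= 2L && all(is.finite(x)),
             sprintf("%s must be a finite numeric vector of length >= 2", what))
  check_that(all(diff(x) > 0), sprintf("%s must be strictly increasing", what))
}

#' Derive an independent RNG stream seed from a base seed and a label
#'
#' Every stochastic generator in the package draws from its own stream,
#' derived deterministically from the user's seed and the generator name, so
#' fixtures never share or perturb each other's random numbers. The result
#' always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param label character stream label (conventionally the generator name).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  check_that(is_number(seed), "seed must be a single finite number")
  h <- 0
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% 2147483647
  s <- (abs(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483645 + 1)
}

# Evaluate expr with a local RNG state; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal quadrature on an arbitrary strictly increasing grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Linear interpolation of (x, y) onto grid xout, NA outside the support.
interp_linear <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 1)$y
}
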