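#' @importFrom stats median quantile rnorm rgamma rnbinom runif sd var
#'   t.test wilcox.test kruskal.test aov anova fft mvfft pt approx
#' @importFrom utils head tail
NULL

# Internal parameter checks. `what` is the user-facing argument name so error
# messages point at the caller's input, not internals.
stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", what)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", what, lower, upper, x)
  invisible(x)
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be TRUE or FALSE", what)
  invisible(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; all generators route their randomness through this.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Cumulative trapezoidal integral, same length as y, starting at 0.
cumtrapz1 <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
}
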