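`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boxcar-smooth a numeric series
#'
#' Moving average with edge replication so the series keeps its length and
#' the ends are not pulled toward zero. Even windows are widened to the next
#' odd integer so the filter stays centred.
#'
#' @param y numeric vector.
#' @param window window width in samples; `window <= 1` returns `y` unchanged.
#' @return numeric vector, same length as `y`.
#' @export
boxcar_smooth <- function(y, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) window <- window + 1L
  hw <- (window - 1L) %/% 2L
  n <- length(y)
  ypad <- c(rep(y[1L], hw), y, rep(y[n], hw))
  sm <- as.numeric(stats::filter(ypad, rep(1 / window, window), sides = 2))
  sm[(hw + 1L):(hw + n)]
}

#' Two-tailed Welch t-test (convenience wrapper)
#'
#' Thin wrapper around [stats::t.test()] with two-tailed alternative and
#' unequal variances, the convention used for all group comparisons here.
#'
#' @param x,y numeric samples.
#' @return the `htest` object from [stats::t.test()].
#' @export
welch_t_test <- function(x, y) {
  stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
}

# half-up rounding to the printed precision; used only at the reporting layer
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(abs(x) * p + 0.5) / p * sign(x)
}
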