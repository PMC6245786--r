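#' Locally weighted polynomial regression (tricube kernel)
#'
#' In-package LOESS smoother used for the windowed homozygosity ratio track.
#' At each abscissa `x[i]` a polynomial of degree `degree` is fitted by
#' weighted least squares over the `ceiling(span * n)` nearest points, with
#' tricube weights `w = (1 - (|x - x[i]| / h)^3)^3` where `h` is the distance
#' to the farthest neighbour; the fitted value is the local polynomial
#' evaluated at `x[i]`.  Optional robustness iterations reweight the fit by
#' the bisquare of scaled residuals.
#'
#' The neighbourhood is forced to hold at least `degree + 2` points so every
#' local fit is determined.
#'
#' @param x strictly increasing abscissae (window centres, bp).
#' @param y response (smoothed ratio track).
#' @param span fraction of points per local neighbourhood, `0 < span <= 1`
#'   (default 0.3).
#' @param degree local polynomial degree (default 1).
#' @param iterations robustness iterations (default 0).
#' @return numeric vector of fitted values at each `x`.
#' @export
loess_fit <- function(x, y, span = 0.3, degree = 1L, iterations = 0L) {
  n <- length(x)
  abort_if(length(y) != n, "x and y lengths differ")
  abort_if(any(diff(x) <= 0), "x must be strictly increasing")
  abort_if(span <= 0 || span > 1, "span must be in (0, 1]")
  abort_if(degree < 0, "degree must be >= 0")
  abort_if(n < degree + 2, "need at least degree + 2 points")
  k <- min(n, max(as.integer(ceiling(span * n)), degree + 2L))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (iter in 0:iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      idx <- order(d)[seq_len(k)]
      h <- max(d[idx])
      w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, k)
      w <- w * rw[idx]
      pos <- w > 0
      if (sum(pos) < degree + 1) {
        # robustness weights zeroed the whole neighbourhood (near-exact fit
        # elsewhere): fall back to the plain kernel weights
        w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, k)
        pos <- w > 0
      }
      xi <- x[idx][pos] - x[i]
      X <- outer(xi, 0:degree, `^`)
      f <- stats::lm.wfit(X, y[idx][pos], w[pos])
      fit[i] <- f$coefficients[1L]
    }
    if (iter < iterations) {
      res <- y - fit
      s <- stats::median(abs(res))
      rw <- if (s > 0) pmax(1 - (res / (6 * s))^2, 0)^2 else rep(1, n)
    }
  }
  fit
}
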