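#' Fit a not-a-knot cubic interpolating spline
#'
#' Constructs the piecewise cubic polynomial
#' \eqn{s(x) = a_i + b_i (x - x_i) + c_i (x - x_i)^2 + d_i (x - x_i)^3}
#' on each knot interval, with continuous first and second derivatives at the
#' interior knots. The free end conditions are the not-a-knot conditions
#' (third derivative continuous across the second and the second-to-last
#' knot), so the interpolant reproduces any polynomial of degree three or
#' less exactly.
#'
#' @param xs numeric vector of strictly increasing abscissae (at least 4).
#' @param ys numeric vector of ordinates (joint angles in degrees), same
#'   length as `xs`, all finite.
#' @return an object of class `cubic_spline` with components `x` (knots) and
#'   `coef`, a matrix with columns `a`, `b`, `c`, `d` (one row per interval).
#' @seealso [predict.cubic_spline()], [resample_to_cycle()]
#' @export
fit_cubic_spline <- function(xs, ys) {
  xs <- as.numeric(xs)
  ys <- as.numeric(ys)
  n <- length(xs)
  if (n < 4L) {
    stop("cubic spline with not-a-knot ends needs at least 4 points, got ", n)
  }
  if (length(ys) != n) stop("xs and ys must have equal length")
  if (anyNA(xs) || anyNA(ys) || !all(is.finite(c(xs, ys)))) {
    stop("xs and ys must be finite")
  }
  h <- diff(xs)
  if (any(h <= 0)) stop("xs must be strictly increasing (duplicate or unsorted abscissae)")

  # Solve for the second derivatives sigma_i at the knots. Interior rows are
  # the usual C2-continuity equations; the first and last rows impose
  # third-derivative continuity at x_2 and x_{n-1} (not-a-knot).
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  slope <- diff(ys) / h
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- h[i - 1L]
    A[i, i]      <- 2 * (h[i - 1L] + h[i])
    A[i, i + 1L] <- h[i]
    rhs[i] <- 6 * (slope[i] - slope[i - 1L])
  }
  A[1L, 1:3] <- c(h[2L], -(h[1L] + h[2L]), h[1L])
  A[n, (n - 2L):n] <- c(h[n - 1L], -(h[n - 2L] + h[n - 1L]), h[n - 2L])
  sigma <- solve(A, rhs)

  i <- seq_len(n - 1L)
  coef <- cbind(
    a = ys[i],
    b = slope - h * (2 * sigma[i] + sigma[i + 1L]) / 6,
    c = sigma[i] / 2,
    d = (sigma[i + 1L] - sigma[i]) / (6 * h)
  )
  structure(list(x = xs, coef = coef), class = "cubic_spline")
}

#' Evaluate a fitted cubic spline
#'
#' @param object a `cubic_spline` from [fit_cubic_spline()].
#' @param newdata numeric vector of query points; must lie inside the knot
#'   span (the spline never extrapolates).
#' @param ... unused.
#' @return numeric vector of interpolated values.
#' @export
predict.cubic_spline <- function(object, newdata, ...) {
  x <- object$x
  tol <- 1e-10 * max(1, diff(range(x)))
  if (any(newdata < x[1L] - tol | newdata > x[length(x)] + tol)) {
    stop("query point outside the knot span [", x[1L], ", ", x[length(x)],
         "]; extrapolation is not supported")
  }
  q <- pmin(pmax(newdata, x[1L]), x[length(x)])
  idx <- findInterval(q, x, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(x) - 1L)
  dx <- q - x[idx]
  cf <- object$coef
  cf[idx, "a"] + dx * (cf[idx, "b"] + dx * (cf[idx, "c"] + dx * cf[idx, "d"]))
}

#' @export
print.cubic_spline <- function(x, ...) {
  cat("Not-a-knot cubic spline:", length(x$x), "knots on [",
      format(x$x[1]), ",", format(x$x[length(x$x)]), "]\n")
  invisible(x)
}

#' Resample a gait-cycle segment to a fixed number of points
#'
#' Time-normalizes one segmented gait cycle: the segment's angle samples are
#' interpolated with a not-a-knot cubic spline and evaluated on a uniform
#' grid of `n_points` query points spanning exactly the segment's abscissa
#' range (interpolation only, never extrapolation). With the default
#' `n_points = 101` the output is the conventional 0-100% gait cycle in 1%
#' steps.
#'
#' @param values numeric vector of angle samples over one gait cycle.
#' @param xs abscissae of the samples (sample index or time); defaults to
#'   `seq_along(values)`.
#' @param n_points length of the normalized output (>= 4).
#' @return numeric vector of length `n_points`; its first and last elements
#'   equal the segment's endpoint values.
#' @export
resample_to_cycle <- function(values, xs = seq_along(values), n_points = 101L) {
  if (n_points < 4L) stop("n_points must be at least 4")
  sp <- fit_cubic_spline(xs, values)
  grid <- seq(xs[1L], xs[length(xs)], length.out = n_points)
  out <- predict(sp, grid)
  # endpoints are knots: return them exactly
  out[1L] <- values[1L]
  out[n_points] <- values[length(values)]
  out
}
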