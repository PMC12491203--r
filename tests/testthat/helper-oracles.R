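# Independent brute-force oracles used to pin down the implementations.

# O(N^2) sample-entropy oracle: plain nested loops, no shared code with
# sample_entropy().
sampen_bruteforce <- function(x, m = 2L, r) {
  N <- length(x)
  count_for <- function(len) {
    n_tpl <- N - m  # same template count at both lengths
    matches <- 0L
    for (i in seq_len(n_tpl)) {
      for (j in seq_len(n_tpl)) {
        if (i == j) next
        d <- max(abs(x[i:(i + len - 1L)] - x[j:(j + len - 1L)]))
        if (d <= r) matches <- matches + 1L
      }
    }
    matches
  }
  a <- count_for(m)
  b <- count_for(m + 1L)
  -log(b / a)
}

# Monte-Carlo polygon area by rejection sampling with a ray-crossing
# point-in-polygon test.
mc_polygon_area <- function(px, py, n_points = 2e5) {
  xr <- range(px); yr <- range(py)
  qx <- stats::runif(n_points, xr[1], xr[2])
  qy <- stats::runif(n_points, yr[1], yr[2])
  n <- length(px)
  inside <- rep(FALSE, n_points)
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > qy) != (py[j] > qy)
    xint <- (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, cross & (qx < xint))
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

random_convex_polygon <- function(n_vertices = 12L) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 2, 10)
  list(x = rad * cos(ang) + stats::runif(1, -5, 5),
       y = rad * sin(ang) + stats::runif(1, -5, 5))
}

# a smooth synthetic gait cycle for geometry/entropy tests
make_test_cycle <- function(n = 101L, stance_fraction = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- seq(0, 1, length.out = n)
  structure(list(
    hip = 16 + 18 * cos(2 * pi * u),
    knee = 22 + 30 * exp(-0.5 * ((u - 0.72) / 0.1)^2) + 8 * exp(-0.5 * ((u - 0.15) / 0.06)^2),
    ankle = 2 * cos(2 * pi * u) - 20 * exp(-0.5 * ((u - stance_fraction) / 0.035)^2),
    stance_fraction = stance_fraction, n_points = as.integer(n)
  ), class = "gait_cycle")
}
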