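test_that("perimeter and area are exact on canonical shapes", {
  sq_x <- c(0, 1, 1, 0); sq_y <- c(0, 0, 1, 1)
  expect_equal(cyclogram_perimeter(sq_x, sq_y), 4)
  expect_equal(cyclogram_area(sq_x, sq_y), 1)
  expect_equal(cyclogram_perimeter(3.2, -1), 0)
  expect_equal(as.numeric(cyclogram_area(c(0, 1), c(0, 1))), 0)
  expect_equal(cyclogram_area(c(0, 1, 2), c(0, 1, 2)), 0)  # collinear
})

test_that("circle perimeter and area match the inscribed-polygon closed forms", {
  n <- 1000L; r <- 10
  th <- 2 * pi * (seq_len(n) - 1) / n
  px <- r * cos(th); py <- r * sin(th)
  expect_equal(cyclogram_perimeter(px, py), n * 2 * r * sin(pi / n), tolerance = 1e-10)
  expect_equal(cyclogram_area(px, py), (n / 2) * r^2 * sin(2 * pi / n), tolerance = 1e-10)
  expect_lt(abs(cyclogram_perimeter(px, py) - 2 * pi * r), 1e-3)
  expect_lt(abs(cyclogram_area(px, py) - pi * r^2), 1e-2)
})

test_that("geometry is invariant under translation, cyclic shift, and reversal flips sign", {
  set.seed(21)
  poly <- random_convex_polygon(15)
  p0 <- cyclogram_perimeter(poly$x, poly$y)
  a0 <- cyclogram_area(poly$x, poly$y)
  expect_equal(cyclogram_perimeter(poly$x + 137.5, poly$y - 42.1), p0, tolerance = 1e-9)
  expect_equal(cyclogram_area(poly$x + 137.5, poly$y - 42.1), a0, tolerance = 1e-9)
  sh <- c(6:15, 1:5)
  expect_equal(cyclogram_perimeter(poly$x[sh], poly$y[sh]), p0, tolerance = 1e-12)
  expect_equal(cyclogram_area(poly$x[sh], poly$y[sh]), a0, tolerance = 1e-12)
  expect_equal(signed_area(rev(poly$x), rev(poly$y)),
               -signed_area(poly$x, poly$y), tolerance = 1e-12)
})

test_that("shoelace area agrees with Monte-Carlo area within 1% on convex polygons", {
  set.seed(33)
  for (k in 1:3) {
    poly <- random_convex_polygon(10 + k)
    a <- cyclogram_area(poly$x, poly$y)
    mc <- mc_polygon_area(poly$x, poly$y, 2e5)
    expect_lt(abs(a - mc) / a, 0.01)
  }
})

test_that("cyclograms label phases by stance fraction and run clockwise", {
  cy <- make_test_cycle(101, 0.6)
  cg <- build_cyclogram(cy)
  expect_equal(sum(cg$phase == "stance"), 61L)
  expect_equal(sum(cg$phase == "swing"), 40L)
  expect_lte(signed_area(cg$hip, cg$knee), 0)  # clockwise traversal
  degen <- make_test_cycle(20)
  degen$hip[] <- 1; degen$knee[] <- 2
  expect_true(attr(build_cyclogram(degen), "degenerate"))
})

test_that("stance + swing equals total identically for perimeter and area", {
  set.seed(44)
  for (k in 1:20) {
    n <- sample(4:40, 1)
    cy <- list(hip = rnorm(n, 0, 20), knee = rnorm(n, 10, 15),
               stance_fraction = runif(1, 0.2, 0.8), n_points = n)
    cg <- suppressWarnings(build_cyclogram(cy))
    d <- phase_decompose(cg)
    expect_identical(d$perimeter_stance + d$perimeter_swing, d$perimeter_total)
    expect_identical(d$area_stance + d$area_swing, d$area_total)
    expect_gte(d$area_total, 0)
  }
  # all points labelled stance: swing holds only the closing segment
  cy <- make_test_cycle(50, stance_fraction = 1)
  d <- phase_decompose(build_cyclogram(cy))
  close_len <- sqrt(diff(cy$hip[c(50, 1)])^2 + diff(cy$knee[c(50, 1)])^2)
  expect_equal(d$perimeter_swing, close_len)
  expect_equal(d$perimeter_stance, d$perimeter_total - close_len)
})

test_that("published group means are additive across phases within rounding", {
  ref <- reference_group_means()
  g <- function(feat, grp) ref[ref$feature == feat, paste0(grp, "_mean")]
  for (grp in c("healthy", "koa")) {
    expect_lt(abs(g("perimeter_stance", grp) + g("perimeter_swing", grp) -
                    g("perimeter_total", grp)), 0.02)
    expect_lt(abs(g("area_stance", grp) + g("area_swing", grp) -
                    g("area_total", grp)), 0.1)
  }
})

test_that("centroid and range of motion equal their closed forms", {
  cy <- make_test_cycle(101)
  expect_equal(cyclogram_centroid(cy),
               c(hip_com = mean(cy$hip), knee_com = mean(cy$knee)))
  expect_equal(unname(range_of_motion(list(hip = seq(0, 10, 0.5), knee = rep(4, 21)))),
               c(10, 0))
  u <- seq(0, 1, length.out = 5001)
  cy2 <- list(hip = 30.7 * sin(2 * pi * u), knee = 5 + 0 * u)
  expect_lt(abs(range_of_motion(cy2)[["hip_rom"]] - 61.4), 0.1)
  expect_error(cyclogram_centroid(list(hip = numeric(0), knee = numeric(0))), "empty")
})

test_that("subject-level aggregation averages per-cycle features symmetrically", {
  c1 <- make_test_cycle(101, 0.58)
  c2 <- make_test_cycle(101, 0.63)
  c2$knee <- c2$knee * 1.3
  f1 <- cyclogram_features(c1); f2 <- cyclogram_features(c2)
  agg <- aggregate_features(list(c1, c2))
  expect_equal(agg, (f1 + f2) / 2)
  expect_equal(aggregate_features(list(c2, c1)), agg)
  expect_equal(aggregate_features(list(c1)), f1)
  expect_error(aggregate_features(list()), "no cycles")
  # two cycles with known areas average exactly
  expect_equal(unname(agg["area_total"]),
               (f1[["area_total"]] + f2[["area_total"]]) / 2)
})
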