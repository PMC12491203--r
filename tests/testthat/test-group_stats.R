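make_fm <- function(y, g, covariates = NULL, feature = "f1") {
  feats <- data.frame(y); names(feats) <- feature
  feature_matrix(sprintf("S%03d", seq_along(y)), g, feats,
                 covariates = covariates,
                 categories = setNames("other", feature))
}

test_that("separated groups are detected and pairwise tests are gated on the omnibus", {
  set.seed(61)
  n <- 20
  g <- rep(c("Healthy", "KOA", "TKA"), each = n)
  y <- rnorm(3 * n) + rep(c(0, 3, 6), each = n)  # 3 pooled-SD shifts
  res <- compare_groups(make_fm(y, g))
  expect_lt(res$kw_p, 0.001)
  expect_true(all(res$sig_HvsK, res$sig_HvsT, res$sig_KvsT))
  expect_true(all(res$p_HvsK < 0.017, res$p_HvsT < 0.017, res$p_KvsT < 0.017))

  # identical distributions: omnibus ~ 1, pairwise not run
  y0 <- rep(rnorm(n), 3)
  res0 <- compare_groups(make_fm(y0, g))
  expect_gt(res0$kw_p, 0.9)
  expect_true(all(is.na(c(res0$p_HvsK, res0$p_HvsT, res0$p_KvsT))))

  # all p-values in [0, 1]
  ps <- unlist(res[grep("_p|p_", names(res))])
  ps <- ps[!is.na(ps)]
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("tiny groups are skipped with a warning and categoricals use Fisher", {
  g <- c(rep("Healthy", 2), rep("KOA", 10), rep("TKA", 10))
  expect_warning(res <- compare_groups(make_fm(rnorm(22), g)), "fewer than 3")
  expect_equal(nrow(res), 0L)
  set.seed(2)
  fm <- make_fm(sample(c("A", "B"), 30, replace = TRUE),
                rep(c("Healthy", "KOA", "TKA"), each = 10))
  res <- compare_groups(fm)
  expect_equal(res$test, "fisher")
  expect_true(res$kw_p >= 0 && res$kw_p <= 1)
})

test_that("ANCOVA with no covariates reduces to one-way ANOVA", {
  set.seed(71)
  y <- rnorm(30) + rep(c(0, 1, 2), each = 10)
  g <- rep(c("Healthy", "KOA", "TKA"), each = 10)
  fm <- make_fm(y, g)
  res <- ancova_adjust(fm, covariates = character(0))
  ref <- summary(aov(y ~ factor(g)))[[1]]
  expect_equal(res$ancova_F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$ancova_p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("ANCOVA F and partial eta squared match a sums-of-squares oracle", {
  set.seed(81)
  n <- 12
  g <- factor(rep(c("Healthy", "KOA", "TKA"), each = 4), levels = c("Healthy", "KOA", "TKA"))
  age <- round(runif(n, 45, 75))
  y <- 10 + 0.2 * age + c(0, 1.5, 3)[as.integer(g)] + rnorm(n)
  fm <- make_fm(y, g, covariates = data.frame(age = age))
  res <- ancova_adjust(fm, covariates = "age")

  # independent oracle: explicit least-squares projections
  X_full <- cbind(1, g == "KOA", g == "TKA", age)
  X_red <- cbind(1, age)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  ss_group <- rss(X_red) - rss(X_full)   # type-II SS for the factor
  ss_res <- rss(X_full)
  df_res <- n - ncol(X_full)
  F_or <- (ss_group / 2) / (ss_res / df_res)
  expect_equal(res$ancova_F, F_or, tolerance = 1e-8)
  expect_equal(res$partial_eta_sq, ss_group / (ss_group + ss_res), tolerance = 1e-8)
  expect_true(res$partial_eta_sq >= 0 && res$partial_eta_sq <= 1)
  # Tukey contrasts attached for the significant effect
  expect_true("f1" %in% names(attr(res, "tukey")) || res$ancova_p >= 0.05)
})

test_that("pure covariate effects yield null-level group effect sizes", {
  set.seed(91)
  etas <- replicate(500, {
    n <- 30
    g <- rep(c("Healthy", "KOA", "TKA"), each = 10)
    age <- rnorm(n, 60, 10)
    y <- 0.5 * age + rnorm(n)  # zero group effect
    fm <- make_fm(y, g, covariates = data.frame(age = age))
    ancova_adjust(fm, covariates = "age")$partial_eta_sq
  })
  # under the null, partial eta^2 ~ Beta(df_g/2, df_res/2); mean df_g/(df_g+df_res)
  expect_lt(abs(mean(etas) - 2 / (2 + 26)), 3 * sd(etas) / sqrt(500))
})

test_that("constant covariates are dropped and side adjustment degrades gracefully", {
  set.seed(55)
  y <- rnorm(30) + rep(c(0, 2, 4), each = 10)
  g <- rep(c("Healthy", "KOA", "TKA"), each = 10)
  fm <- make_fm(y, g, covariates = data.frame(age = rep(60, 30),
                                              side_category = rep("none", 30)))
  expect_warning(res <- ancova_adjust(fm, covariates = "age"), "constant")
  ref <- ancova_adjust(fm, covariates = character(0))
  expect_equal(res$ancova_F, ref$ancova_F)
  # identical side for everyone: reduces to the unadjusted model exactly
  expect_warning(side <- side_adjusted_ancova(fm), "constant")
  expect_equal(side$ancova_F, ref$ancova_F)
})

test_that("side-driven variance is absorbed by side adjustment", {
  set.seed(65)
  n <- 36
  g <- rep(c("Healthy", "KOA", "TKA"), each = 12)
  side <- rep(rep(c("unilateral_left", "unilateral_right", "bilateral"), each = 4), 3)
  y <- c(unilateral_left = 0, unilateral_right = 5, bilateral = 10)[side] + rnorm(n, 0, 0.3)
  fm <- make_fm(y, g, covariates = data.frame(side_category = side))
  res <- side_adjusted_ancova(fm)
  # null-level group effect (partial eta^2 ~ Beta with mean df_g/(df_g+df_res)
  # ~ 0.06 here), far below the side-driven unadjusted value
  expect_lt(res$partial_eta_sq, 0.2)
  expect_gt(res$ancova_p, 0.1)
  # dummy-coding k categories adds k-1 design columns
  fit <- lm(y ~ factor(g) + factor(side))
  expect_equal(length(coef(fit)), 1 + 2 + 2)
  # singleton category is merged with a warning
  side2 <- side; side2[1] <- "none"
  fm2 <- make_fm(y, g, covariates = data.frame(side_category = side2))
  expect_warning(side_adjusted_ancova(fm2), "merged")
})

test_that("percent change reproduces the worked group-mean summaries", {
  expect_equal(round(percent_change(34.40, 21.08), 1), -38.7)
  expect_equal(round(percent_change(0.24, 0.30), 1), 25.0)
  expect_equal(percent_change(7.3, 7.3), 0)
  expect_error(percent_change(0, 5), "nonzero")
})
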