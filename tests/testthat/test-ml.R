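test_that("feature sets split by category with the fused union", {
  fm <- default_fm()
  sets <- assemble_feature_sets(fm)
  expect_named(sets, c("fused", "cyclogram", "entropy", "spatiotemporal"))
  expect_equal(ncol(sets$fused), 13L)
  expect_equal(ncol(sets$cyclogram), 10L)
  expect_setequal(names(sets$entropy), c("se_hip", "se_knee", "se_ankle"))
  expect_equal(ncol(sets$spatiotemporal), 5L)
  expect_setequal(names(sets$fused), union(names(sets$cyclogram), names(sets$entropy)))
  expect_false(anyDuplicated(names(sets$fused)) > 0)
  fm2 <- fm
  fm2$categories[fm2$categories == "entropy"] <- "cyclogram"
  expect_error(assemble_feature_sets(fm2), "entropy")
})

test_that("fold preprocessing fits on train only and standardizes exactly", {
  set.seed(31)
  train <- data.frame(a = c(1, 2, NA, 4, 8), b = rnorm(5))
  test <- data.frame(a = c(2, NA), b = c(0, 1))
  pp <- preprocess_fold(train, test)
  # NA imputed with the train median, then Z-scored
  expect_false(anyNA(pp$train))
  expect_false(anyNA(pp$test))
  expect_equal(unname(pp$medians["a"]), median(c(1, 2, 4, 8)))
  expect_equal(colMeans(pp$train), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(pp$train, sd, numeric(1)), c(a = 1, b = 1), tolerance = 1e-12)
  # a test value equal to the train mean maps to zero
  probe <- data.frame(a = pp$center[["a"]], b = pp$center[["b"]])
  expect_equal(unlist(preprocess_fold(train, probe)$test), c(a = 0, b = 0),
               tolerance = 1e-12)
  # leakage probe: perturbing the test fold never changes fitted parameters
  pp2 <- preprocess_fold(train, test * 1000 + 7)
  expect_identical(pp2$medians, pp$medians)
  expect_identical(pp2$center, pp$center)
  expect_identical(pp2$scale, pp$scale)
  expect_identical(pp2$train, pp$train)
  # zero-variance columns are dropped with a warning
  train$z <- 5
  expect_warning(pp3 <- preprocess_fold(train, cbind(test, z = 5)), "zero-variance")
  expect_false("z" %in% names(pp3$train))
})

test_that("ANOVA-F selection finds informative columns and ranks constants last", {
  set.seed(41)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = 20))
  X <- as.data.frame(matrix(rnorm(n * 12), n))
  names(X) <- paste0("f", 1:12)
  X$f3 <- X$f3 + 5 * (as.integer(y) - 1)  # 5-SD separations
  X$f7 <- X$f7 + 5 * (y == "b")
  sel <- select_top_features(X, y, k = 10)
  expect_true(all(c("f3", "f7") %in% sel))
  expect_length(sel, 10L)
  expect_equal(sort(select_top_features(X[, 1:3], y, k = 10)), c("f1", "f2", "f3"))
  X$const <- 1
  expect_equal(tail(select_top_features(X, y, k = ncol(X)), 1), "const")
  expect_error(select_top_features(X, factor(rep("a", n)), 5), "2 classes")
})

test_that("stratified folds deviate from proportionality by at most one subject", {
  set.seed(51)
  y <- factor(rep(c("Healthy", "KOA", "TKA"), c(21, 24, 25)))
  folds <- stratified_folds(y, 5)
  for (lv in levels(y)) {
    counts <- table(factor(folds[y == lv], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("each classifier fits, predicts probabilities, and ranks the informative feature first", {
  set.seed(61)
  n <- 90
  y <- factor(rep(c("a", "b", "c"), each = 30))
  X <- data.frame(sig = 6 * (as.integer(y) - 1) + rnorm(n),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  for (mdl in c("rf", "svm", "dt", "knn")) {
    fit <- fit_classifier(mdl, X, y, seed = 5)
    pred <- predict(fit, X)
    expect_equal(levels(pred$class), levels(y))
    expect_equal(dim(pred$prob), c(n, 3L))
    expect_equal(unname(rowSums(pred$prob)), rep(1, n), tolerance = 1e-6)
    expect_gt(mean(pred$class == y), 0.9)
    imp <- compute_importances(fit, X, y, n_shuffles = 20, seed = 5)
    expect_equal(imp$feature[1], "sig")
    if (mdl %in% c("rf", "dt")) {
      full <- compute_importances(fit, top = 4)
      expect_true(all(full$importance >= 0))
      expect_equal(sum(full$importance), 1, tolerance = 1e-9)
    } else {
      # permutation importance of uninformative features stays near zero
      expect_true(all(abs(imp$importance[imp$feature != "sig"]) < 0.1))
    }
  }
  expect_error(fit_classifier("mlp", X, y), "RF, SVM, DT, KNN")
})

test_that("nested CV is deterministic and leak-free", {
  sep <- separable_matrix(c(10L, 10L, 10L), delta = 4, seed = 7)
  a <- nested_cv_evaluate(sep$x, sep$y, "dt", seed = 99)
  b <- nested_cv_evaluate(sep$x, sep$y, "dt", seed = 99)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$oof, b$oof)
  expect_identical(a$chosen, b$chosen)
  c2 <- nested_cv_evaluate(sep$x, sep$y, "dt", seed = 100)
  expect_s3_class(c2, "cv_result")
  expect_true(all(a$metrics[c("accuracy", "precision", "recall", "f1")] <= 100))
  expect_error(nested_cv_evaluate(sep$x, sep$y, "boost", seed = 1), "RF, SVM, DT, KNN")
})

test_that("bootstrap AUC behaves at the extremes and tightens with n", {
  make_cv <- function(n, noise) {
    set.seed(3)
    y <- factor(rep(c("a", "b", "c"), length.out = n))
    prob <- matrix(0.01, n, 3, dimnames = list(NULL, levels(y)))
    prob[cbind(seq_len(n), as.integer(y))] <- 1
    prob <- prob + matrix(abs(rnorm(3 * n, 0, noise)), n, 3)
    prob <- prob / rowSums(prob)
    structure(list(oof = list(truth = y, prob = prob,
                              class = factor(levels(y)[max.col(prob)], levels(y)))),
              class = "cv_result")
  }
  perfect <- bootstrap_auc(make_cv(60, 0), B = 100, seed = 1)
  expect_equal(perfect$auc, 1)
  expect_equal(unname(perfect$ci), c(1, 1))
  # random probabilities: AUC near 0.5 with a covering interval
  set.seed(4)
  n <- 90
  y <- factor(rep(c("a", "b", "c"), each = 30))
  prob <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, levels(y)))
  prob <- prob / rowSums(prob)
  rnd <- structure(list(oof = list(truth = y, prob = prob)), class = "cv_result")
  bs <- bootstrap_auc(rnd, B = 300, seed = 2)
  expect_lt(abs(bs$auc - 0.5), 0.12)
  expect_true(bs$ci[1] <= 0.5 && bs$ci[2] >= 0.5)
  # interval width shrinks when the cohort grows tenfold
  w70 <- diff(bootstrap_auc(make_cv(70, 0.8), B = 300, seed = 5)$ci)
  w700 <- diff(bootstrap_auc(make_cv(700, 0.8), B = 300, seed = 5)$ci)
  expect_lt(w700, w70)
})

test_that("LDA baseline separates separable cohorts and not permuted ones", {
  sep <- separable_matrix(delta = 5, seed = 11)
  expect_gt(lda_baseline(sep$x, sep$y, seed = 1), 95)
  set.seed(12)
  yperm <- sample(sep$y)
  acc <- lda_baseline(sep$x, yperm, seed = 1)
  expect_lt(abs(acc - 100 / 3), 15)
})
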