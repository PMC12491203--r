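# Machine-learning evaluation harness: four feature categories (fused =
# cyclogram + entropy, cyclogram only, entropy only, spatiotemporal only)
# evaluated with four classifiers (RF, SVM, DT, KNN) under nested stratified
# cross-validation. Outer 5-fold stratified CV estimates performance; per
# outer fold, median imputation, Z-score standardization, and top-k ANOVA
# F-statistic feature selection are fitted on the training fold only, and an
# inner 3-fold CV picks hyperparameters from the configured ranges. Classes
# are weighted inversely proportional to their frequency. Metrics are pooled
# over the outer test folds: accuracy, weighted precision/recall/F1 (in
# percent), and macro one-vs-rest AUC with bootstrap confidence intervals.

MODEL_NAMES <- c("rf", "svm", "dt", "knn")

#' Default hyperparameter search ranges
#'
#' RF: number of trees 50-100 and maximum depth 3-5, explored by random
#' search (20 draws). SVM: RBF kernel with cost 0.1-10. DT: maximum depth
#' 3-5 with the Gini splitting criterion. KNN: 3-7 neighbours with
#' distance weighting.
#'
#' @param rf_search `"random"` (default, 20 draws) or `"grid"`.
#' @return named list of per-model search specifications.
#' @export
default_grids <- function(rf_search = c("random", "grid")) {
  rf_search <- match.arg(rf_search)
  list(
    rf = list(num_trees = 50:100, max_depth = 3:5,
              search = rf_search, n_draws = 20L),
    svm = list(cost = c(0.1, 0.3, 1, 3, 5, 10), kernel = "radial"),
    dt = list(max_depth = 3:5, split = "gini"),
    knn = list(k = 3:7, weight = "distance")
  )
}

#' Split a feature matrix into the four evaluation feature sets
#'
#' @param fm a [feature_matrix()].
#' @return named list of data frames: `fused` (cyclogram + entropy),
#'   `cyclogram`, `entropy`, `spatiotemporal`. Errors if a category has no
#'   columns.
#' @export
assemble_feature_sets <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  cats <- fm$categories
  pick <- function(which) names(cats)[cats %in% which]
  sets <- list(fused = pick(c("cyclogram", "entropy")),
               cyclogram = pick("cyclogram"),
               entropy = pick("entropy"),
               spatiotemporal = pick("spatiotemporal"))
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0L]
  if (length(empty)) stop("feature category with no columns: ", paste(empty, collapse = ", "))
  lapply(sets, function(cols) fm$features[, cols, drop = FALSE])
}

#' Fold-wise preprocessing: median imputation and Z-score standardization
#'
#' Imputation medians and standardization parameters are estimated on the
#' training fold only and applied to both folds, so no information leaks
#' from the test fold. Zero-variance training columns are dropped with a
#' warning.
#'
#' @param train,test numeric data frames with identical columns (`test` may
#'   be `NULL`).
#' @return list with transformed `train`, `test`, and the fitted parameters
#'   (`medians`, `center`, `scale`, `dropped`).
#' @export
preprocess_fold <- function(train, test = NULL) {
  if (nrow(train) == 0L) stop("training fold is empty")
  medians <- vapply(train, function(v) stats::median(v, na.rm = TRUE), numeric(1))
  impute <- function(df) {
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- medians[[j]]
    df
  }
  train <- impute(train)
  center <- vapply(train, mean, numeric(1))
  scale <- vapply(train, stats::sd, numeric(1))
  dropped <- names(train)[scale < 1e-12 | !is.finite(scale)]
  if (length(dropped)) {
    warning("zero-variance training column(s) dropped: ", paste(dropped, collapse = ", "))
  }
  keep <- setdiff(names(train), dropped)
  z <- function(df) {
    df <- impute(df)[, keep, drop = FALSE]
    as.data.frame(Map(function(v, m, s) (v - m) / s, df, center[keep], scale[keep]),
                  col.names = keep, check.names = FALSE)
  }
  out_train <- z(train)
  out_test <- if (!is.null(test)) z(test) else NULL
  list(train = out_train, test = out_test, medians = medians,
       center = center[keep], scale = scale[keep], dropped = dropped)
}

#' Select the top-k features by one-way ANOVA F statistic
#'
#' @param train numeric training data frame.
#' @param y class factor for the training rows (>= 2 classes).
#' @param k number of features to keep; all are kept when fewer exist.
#' @return character vector of selected column names, in decreasing F order.
#' @export
select_top_features <- function(train, y, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("feature selection needs at least 2 classes in the training fold")
  f_stat <- vapply(train, function(v) {
    if (length(unique(v)) < 2L) return(0)  # constant column ranks last
    out <- tryCatch(stats::oneway.test(v ~ y, var.equal = TRUE)$statistic,
                    error = function(e) NA_real_)
    if (!is.finite(out)) 0 else as.numeric(out)
  }, numeric(1))
  names(sort(f_stat, decreasing = TRUE))[seq_len(min(k, ncol(train)))]
}

# inverse-frequency class weights (sum over samples of weight = n)
.class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

#' Stratified k-fold assignment
#'
#' Assigns every observation to one of `k` folds so that each fold's class
#' counts deviate from exact proportionality by at most one subject.
#'
#' @param y class factor.
#' @param k number of folds.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k = 5L) {
  y <- as.factor(y)
  folds <- integer(length(y))
  offset <- 0L
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

.check_model_name <- function(model) {
  model <- tolower(model)
  if (!model %in% MODEL_NAMES) {
    stop("unknown model '", model, "'; available models: RF, SVM, DT, KNN")
  }
  model
}

#' Fit one of the four classifiers
#'
#' Thin wrapper giving RF (ranger), SVM (e1071, RBF kernel with per-class
#' penalty weights and pairwise-coupling probability estimates), DT (rpart,
#' Gini) and a distance-weighted KNN a common fit/predict surface with
#' inverse-frequency class weighting.
#'
#' @param model one of `"rf"`, `"svm"`, `"dt"`, `"knn"` (case-insensitive).
#' @param x numeric data frame of predictors.
#' @param y class factor.
#' @param hyper named list of hyperparameters (see [default_grids()]).
#' @param seed integer seed for the stochastic RF fit.
#' @return an object of class `gait_classifier`.
#' @export
fit_classifier <- function(model, x, y, hyper = list(), seed = 1L) {
  model <- .check_model_name(model)
  y <- droplevels(as.factor(y))
  w <- .class_weights(y)
  fit <- switch(model,
    rf = ranger::ranger(x = x, y = y,
                        num.trees = hyper$num_trees %||% 80L,
                        max.depth = hyper$max_depth %||% 4L,
                        probability = TRUE, class.weights = w[levels(y)],
                        importance = "impurity", seed = seed,
                        num.threads = 1L),
    svm = e1071::svm(x = as.matrix(x), y = y, kernel = hyper$kernel %||% "radial",
                     cost = hyper$cost %||% 5, class.weights = w,
                     probability = TRUE),
    dt = {
      dat <- cbind(.y = y, x)
      rpart::rpart(.y ~ ., data = dat, method = "class",
                   weights = as.numeric(w[as.character(y)]),
                   parms = list(split = hyper$split %||% "gini"),
                   control = rpart::rpart.control(maxdepth = hyper$max_depth %||% 3L,
                                                  cp = 0, xval = 0,
                                                  minsplit = 5L, minbucket = 2L))
    },
    knn = list(x = as.matrix(x), y = y, k = hyper$k %||% 5L,
               weight = hyper$weight %||% "distance", class_weights = w)
  )
  structure(list(model = model, fit = fit, levels = levels(y), hyper = hyper,
                 feature_names = names(x)),
            class = "gait_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict classes and class probabilities
#'
#' @param object a [fit_classifier()] result.
#' @param newdata numeric data frame with the training columns.
#' @param ... unused.
#' @return list with `class` (factor) and `prob` (matrix, columns in level
#'   order).
#' @export
predict.gait_classifier <- function(object, newdata, ...) {
  lv <- object$levels
  newdata <- newdata[, object$feature_names, drop = FALSE]
  prob <- switch(object$model,
    rf = stats::predict(object$fit, data = newdata, num.threads = 1L)$predictions,
    svm = {
      pr <- stats::predict(object$fit, as.matrix(newdata), probability = TRUE)
      attr(pr, "probabilities")
    },
    dt = stats::predict(object$fit, newdata, type = "prob"),
    knn = .knn_prob(object$fit, as.matrix(newdata))
  )
  prob <- as.matrix(prob)[, lv, drop = FALSE]
  cls <- factor(lv[max.col(prob, ties.method = "first")], levels = lv)
  list(class = cls, prob = prob)
}

# distance-weighted k-nearest-neighbour class probabilities
.knn_prob <- function(fit, newx) {
  lv <- levels(fit$y)
  out <- matrix(0, nrow(newx), length(lv), dimnames = list(NULL, lv))
  cw <- fit$class_weights[as.character(fit$y)]
  for (i in seq_len(nrow(newx))) {
    d <- sqrt(colSums((t(fit$x) - newx[i, ])^2))
    nn <- order(d)[seq_len(min(fit$k, length(d)))]
    if (fit$weight == "distance") {
      if (any(d[nn] < 1e-12)) {
        w <- as.numeric(d[nn] < 1e-12)  # exact matches dominate
      } else {
        w <- 1 / d[nn]
      }
    } else {
      w <- rep(1, length(nn))
    }
    w <- w * cw[nn]
    votes <- tapply(w, factor(as.character(fit$y[nn]), levels = lv), sum, default = 0)
    out[i, ] <- votes / sum(votes)
  }
  out
}

# enumerate hyperparameter candidates for one model (uses the current RNG
# stream for RF random search)
.hyper_candidates <- function(model, grid) {
  switch(model,
    rf = {
      if (identical(grid$search, "grid")) {
        expand <- expand.grid(num_trees = grid$num_trees, max_depth = grid$max_depth)
        lapply(seq_len(nrow(expand)), function(i) as.list(expand[i, ]))
      } else {
        lapply(seq_len(grid$n_draws %||% 20L), function(i) {
          list(num_trees = sample(grid$num_trees, 1L),
               max_depth = sample(grid$max_depth, 1L))
        })
      }
    },
    svm = lapply(grid$cost, function(cc) list(cost = cc, kernel = grid$kernel %||% "radial")),
    dt = lapply(grid$max_depth, function(d) list(max_depth = d, split = grid$split %||% "gini")),
    knn = lapply(grid$k, function(kk) list(k = kk, weight = grid$weight %||% "distance"))
  )
}

#' Nested stratified cross-validation of one classifier on one feature set
#'
#' Outer 5-fold stratified CV; per outer fold the preprocessing
#' ([preprocess_fold()]) and ANOVA top-k feature selection
#' ([select_top_features()]) are fitted on the training fold, an inner
#' 3-fold stratified CV picks the hyperparameters with the best inner
#' accuracy, and the winning configuration is refitted on the full outer
#' training fold to predict the held-out fold. Out-of-fold predictions are
#' pooled into the reported metrics. Fully reproducible from `seed`.
#'
#' @param x numeric data frame (one feature set view).
#' @param y class factor.
#' @param model `"rf"`, `"svm"`, `"dt"`, or `"knn"` (case-insensitive).
#' @param seed integer master seed.
#' @param grids search ranges, see [default_grids()].
#' @param k_outer,k_inner outer/inner fold counts (defaults 5 and 3).
#' @param top_k ANOVA feature-selection cap (default 10; capped at the
#'   number of available columns).
#' @return object of class `cv_result`: `metrics` (accuracy, weighted
#'   precision/recall/F1 in percent, macro AUC), `oof` (out-of-fold class
#'   probabilities and predictions), `chosen` (per-fold winning
#'   hyperparameters), `selected` (per-fold feature subsets), `seed`.
#' @export
nested_cv_evaluate <- function(x, y, model, seed = 1L, grids = default_grids(),
                               k_outer = 5L, k_inner = 3L, top_k = 10L) {
  model <- .check_model_name(model)
  y <- droplevels(as.factor(y))
  if (any(table(y) < k_outer)) stop("need at least ", k_outer, " subjects per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- stratified_folds(y, k_outer)
  n <- length(y)
  oof_prob <- matrix(NA_real_, n, nlevels(y), dimnames = list(NULL, levels(y)))
  oof_class <- factor(rep(NA, n), levels = levels(y))
  chosen <- vector("list", k_outer)
  selected <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    tr <- folds != f; te <- !tr
    pp <- preprocess_fold(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    sel <- select_top_features(pp$train, y[tr], top_k)
    xtr <- pp$train[, sel, drop = FALSE]
    xte <- pp$test[, sel, drop = FALSE]
    cands <- .hyper_candidates(model, grids[[model]])
    best <- cands[[1L]]
    if (length(cands) > 1L) {
      inner <- stratified_folds(y[tr], k_inner)
      scores <- vapply(cands, function(h) {
        acc <- 0
        for (g in seq_len(k_inner)) {
          itr <- inner != g
          fit <- fit_classifier(model, xtr[itr, , drop = FALSE], y[tr][itr],
                                h, seed = seed + 1000L * f + g)
          pred <- predict(fit, xtr[!itr, , drop = FALSE])$class
          acc <- acc + sum(pred == y[tr][!itr])
        }
        acc / sum(tr)
      }, numeric(1))
      best <- cands[[which.max(scores)]]
    }
    fit <- fit_classifier(model, xtr, y[tr], best, seed = seed + f)
    pred <- predict(fit, xte)
    oof_prob[te, ] <- pred$prob
    oof_class[te] <- pred$class
    chosen[[f]] <- best
    selected[[f]] <- sel
  }
  metrics <- classification_metrics(y, oof_class, oof_prob)
  structure(list(model = model, metrics = metrics,
                 oof = list(prob = oof_prob, class = oof_class, truth = y),
                 chosen = chosen, selected = selected, folds = folds,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Nested CV [%s]: Acc %.2f%%  Pre %.2f%%  Recall %.2f%%  F1 %.2f%%  macro AUC %.4f (seed %d)\n",
              toupper(x$model), m["accuracy"], m["precision"], m["recall"],
              m["f1"], m["auc"], x$seed))
  invisible(x)
}

#' Pooled classification metrics
#'
#' Accuracy and support-weighted precision, recall, and F1 (percent), plus
#' macro one-vs-rest AUC from class probabilities.
#'
#' @param truth factor of true classes.
#' @param pred factor of predicted classes.
#' @param prob matrix of class probabilities (columns in level order), or
#'   `NULL` to skip the AUC.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   (percent) and `auc`.
#' @export
classification_metrics <- function(truth, pred, prob = NULL) {
  lv <- levels(truth)
  support <- as.numeric(table(truth)[lv])
  per <- vapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    c(pr, rc, f1)
  }, numeric(3))
  wts <- support / sum(support)
  auc <- if (is.null(prob)) NA_real_ else macro_auc(truth, prob)
  c(accuracy = 100 * mean(pred == truth, na.rm = TRUE),
    precision = 100 * sum(per[1, ] * wts),
    recall = 100 * sum(per[2, ] * wts),
    f1 = 100 * sum(per[3, ] * wts),
    auc = auc)
}

#' Macro one-vs-rest AUC
#'
#' @param truth factor of true classes.
#' @param prob probability matrix with one column per class level.
#' @return mean of the per-class one-vs-rest AUCs.
#' @export
macro_auc <- function(truth, prob) {
  lv <- levels(truth)
  aucs <- vapply(lv, function(cl) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Feature importances for a fitted classifier
#'
#' Impurity-based importances for RF and DT; seeded permutation importance
#' (mean accuracy drop over shuffles) for SVM and KNN.
#'
#' @param object a [fit_classifier()] result.
#' @param x,y evaluation data (required for the permutation method).
#' @param n_shuffles permutation repeats per feature (default 50).
#' @param seed RNG seed for the permutation method.
#' @param top report the top-`top` features (default 5).
#' @return data frame `feature`, `importance`, decreasing; impurity
#'   importances are normalized to sum to 1.
#' @export
compute_importances <- function(object, x = NULL, y = NULL, n_shuffles = 50L,
                                seed = 1L, top = 5L) {
  stopifnot(inherits(object, "gait_classifier"))
  feats <- object$feature_names
  imp <- switch(object$model,
    rf = {
      v <- ranger::importance(object$fit)
      v[setdiff(feats, names(v))] <- 0
      v <- pmax(v[feats], 0)
      if (sum(v) > 0) v / sum(v) else v
    },
    dt = {
      v <- object$fit$variable.importance
      out <- stats::setNames(rep(0, length(feats)), feats)
      if (!is.null(v)) out[names(v)] <- v
      if (sum(out) > 0) out / sum(out) else out
    },
    {
      if (is.null(x) || is.null(y)) stop("permutation importance needs x and y")
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
      y <- factor(as.character(y), levels = object$levels)
      base_acc <- mean(predict(object, x)$class == y)
      vapply(feats, function(f) {
        drops <- vapply(seq_len(n_shuffles), function(s) {
          xp <- x
          xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
          base_acc - mean(predict(object, xp)$class == y)
        }, numeric(1))
        mean(drops)
      }, numeric(1))
    })
  ord <- order(imp, decreasing = TRUE)
  utils::head(data.frame(feature = feats[ord], importance = as.numeric(imp[ord]),
                         row.names = NULL), top)
}

#' Bootstrap comparison of macro AUC
#'
#' Resamples subjects with replacement from the pooled out-of-fold
#' probabilities and recomputes the macro one-vs-rest AUC, giving a
#' percentile confidence interval. Resamples missing a class are redrawn.
#'
#' @param cv a `cv_result` from [nested_cv_evaluate()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list `auc` (point estimate on the full sample), `ci` (percentile
#'   interval), `boot` (resampled values), `B`, `seed`.
#' @export
bootstrap_auc <- function(cv, B = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(cv, "cv_result"))
  truth <- cv$oof$truth
  prob <- cv$oof$prob
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(truth)
  boot <- vapply(seq_len(B), function(b) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (nlevels(droplevels(truth[idx])) == nlevels(truth)) break
    }
    macro_auc(truth[idx], prob[idx, , drop = FALSE])
  }, numeric(1))
  a <- (1 - conf) / 2
  list(auc = macro_auc(truth, prob),
       ci = stats::quantile(boot, c(a, 1 - a), names = FALSE),
       boot = boot, B = B, seed = seed)
}

#' Linear discriminant baseline accuracy
#'
#' 5-fold stratified cross-validated accuracy of an LDA classifier on one
#' feature-set view, with fold-wise imputation and standardization. Used as
#' the simple linear reference against which the nested-CV models are
#' compared.
#'
#' @param x numeric data frame (feature-set view).
#' @param y class factor.
#' @param seed RNG seed for the fold assignment.
#' @param k folds (default 5).
#' @return accuracy in percent.
#' @export
lda_baseline <- function(x, y, seed = 1L, k = 5L) {
  y <- droplevels(as.factor(y))
  if (any(table(y) < k)) stop("need at least ", k, " subjects per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- stratified_folds(y, k)
  pred <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    pp <- preprocess_fold(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    # phase totals are exact sums of their parts, so collinearity among the
    # cyclogram features is structural, not a data problem
    fit <- withCallingHandlers(
      MASS::lda(pp$train, grouping = y[tr]),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    pred[!tr] <- stats::predict(fit, pp$test)$class
  }
  100 * mean(pred == y)
}
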