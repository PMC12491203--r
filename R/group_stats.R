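# Group-comparison protocol for the feature matrix: Shapiro-Wilk normality
# screening per group, Kruskal-Wallis omnibus test across the three groups,
# pairwise Mann-Whitney U tests gated on omnibus significance and declared at
# the fixed Bonferroni threshold p < 0.017 (0.05/3 as conventionally
# printed), Fisher's exact test for categorical variables, and
# covariate-adjusted ANCOVA with partial eta squared and Tukey HSD.

#' Nonparametric group comparison per feature
#'
#' For every numeric feature: Shapiro-Wilk p per group, Kruskal-Wallis
#' omnibus p across groups, and -- only when the omnibus test is significant
#' at `alpha` -- all three pairwise Mann-Whitney U tests with significance
#' declared at `pairwise_threshold`. Categorical columns are compared with
#' Fisher's exact test against group. Features with any group smaller than 3
#' observations are skipped with a warning.
#'
#' @param fm a [feature_matrix()].
#' @param alpha omnibus significance level (default 0.05).
#' @param pairwise_threshold fixed Bonferroni threshold for the pairwise
#'   tests (default 0.017, i.e. 0.05 over three comparisons).
#' @param columns feature columns to test; defaults to all.
#' @return data frame of class `group_comparison`: one row per feature with
#'   `shapiro_p_*` per group, `kw_p`, pairwise `p_HvsK`, `p_HvsT`, `p_KvsT`
#'   (NA when the omnibus test is not significant) and logical `sig_*` flags.
#' @export
compare_groups <- function(fm, alpha = 0.05, pairwise_threshold = 0.017,
                           columns = names(fm$features)) {
  stopifnot(inherits(fm, "feature_matrix"))
  g <- fm$group
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 groups")
  pairs <- list(HvsK = c("Healthy", "KOA"), HvsT = c("Healthy", "TKA"),
                KvsT = c("KOA", "TKA"))
  rows <- lapply(columns, function(feat) {
    y <- fm$features[[feat]]
    if (!is.numeric(y)) {
      p <- tryCatch(stats::fisher.test(table(y, g))$p.value, error = function(e) NA_real_)
      return(data.frame(feature = feat, test = "fisher",
                        shapiro_p_Healthy = NA, shapiro_p_KOA = NA, shapiro_p_TKA = NA,
                        kw_p = p, p_HvsK = NA, p_HvsT = NA, p_KvsT = NA))
    }
    sizes <- tapply(!is.na(y), g, sum)
    if (any(sizes < 3L, na.rm = TRUE)) {
      warning("feature ", feat, " skipped: a group has fewer than 3 observations")
      return(NULL)
    }
    sw <- vapply(levels(g), function(lv) {
      v <- y[g == lv & !is.na(y)]
      if (length(unique(v)) < 3L) NA_real_ else stats::shapiro.test(v)$p.value
    }, numeric(1))
    kw <- stats::kruskal.test(y, g)$p.value
    pw <- rep(NA_real_, 3L)
    if (is.finite(kw) && kw < alpha) {
      pw <- vapply(pairs, function(pr) {
        stats::wilcox.test(y[g == pr[1L]], y[g == pr[2L]], exact = FALSE)$p.value
      }, numeric(1))
    }
    data.frame(feature = feat, test = "kruskal",
               shapiro_p_Healthy = sw[["Healthy"]], shapiro_p_KOA = sw[["KOA"]],
               shapiro_p_TKA = sw[["TKA"]], kw_p = kw,
               p_HvsK = pw[1L], p_HvsT = pw[2L], p_KvsT = pw[3L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (nm in c("HvsK", "HvsT", "KvsT")) {
    out[[paste0("sig_", nm)]] <- !is.na(out[[paste0("p_", nm)]]) &
      out[[paste0("p_", nm)]] < pairwise_threshold
  }
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "pairwise_threshold") <- pairwise_threshold
  out
}

#' Covariate-adjusted ANCOVA per feature
#'
#' Fits `feature ~ group + covariates` by least squares for every feature
#' and reports the group main-effect F and p (Type II sums of squares by
#' default) together with partial eta squared
#' `SS_group / (SS_group + SS_residual)`. Constant (or otherwise
#' rank-deficient) covariates are dropped with a warning. For significant
#' main effects, Tukey HSD contrasts between group means adjusted to the
#' covariate means are attached.
#'
#' @param fm a [feature_matrix()].
#' @param covariates covariate column names (numeric or categorical) taken
#'   from `fm$covariates`; default `c("age", "sex", "bmi")`. May be empty,
#'   in which case the model reduces to a one-way ANOVA.
#' @param ss_type sums-of-squares type for the group effect: `"II"`
#'   (default), `"I"`, or `"III"`.
#' @param alpha level gating the Tukey HSD post hoc (default 0.05).
#' @param columns feature columns to model; defaults to all numeric features.
#' @return data frame of class `ancova_table`: `feature`, `ancova_F`,
#'   `ancova_p`, `partial_eta_sq`, with a `tukey` attribute (named list of
#'   contrast tables for significant features).
#' @export
ancova_adjust <- function(fm, covariates = c("age", "sex", "bmi"),
                          ss_type = c("II", "I", "III"), alpha = 0.05,
                          columns = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  ss_type <- match.arg(ss_type)
  if (is.null(columns)) {
    columns <- names(fm$features)[vapply(fm$features, is.numeric, logical(1))]
  }
  covar_df <- if (is.null(fm$covariates)) {
    data.frame(row.names = seq_along(fm$subject_id))
  } else fm$covariates
  covars <- covar_df[, intersect(covariates, names(covar_df)), drop = FALSE]
  miss <- setdiff(covariates, names(covar_df))
  if (length(miss)) warning("covariate(s) not present, ignored: ", paste(miss, collapse = ", "))
  # drop constant covariates (rank-deficient design otherwise)
  keep <- vapply(covars, function(v) length(unique(stats::na.omit(v))) > 1L, logical(1))
  if (any(!keep)) {
    warning("constant covariate(s) dropped: ", paste(names(covars)[!keep], collapse = ", "))
    covars <- covars[, keep, drop = FALSE]
  }
  dat0 <- data.frame(group = fm$group, covars)
  dat0[] <- lapply(dat0, function(v) if (is.character(v)) factor(v) else v)
  rhs <- paste(c("group", names(covars)), collapse = " + ")
  tukey <- list()
  rows <- lapply(columns, function(feat) {
    dat <- dat0
    dat$.y <- fm$features[[feat]]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    if (ss_type == "I") {
      an <- stats::anova(fit)
      ss_g <- an["group", "Sum Sq"]; df_g <- an["group", "Df"]
    } else {
      an <- car::Anova(fit, type = ss_type)
      ss_g <- an["group", "Sum Sq"]; df_g <- an["group", "Df"]
    }
    ss_res <- sum(stats::residuals(fit)^2)
    df_res <- stats::df.residual(fit)
    F_g <- (ss_g / df_g) / (ss_res / df_res)
    p_g <- stats::pf(F_g, df_g, df_res, lower.tail = FALSE)
    if (is.finite(p_g) && p_g < alpha) {
      em <- emmeans::emmeans(fit, "group")
      tukey[[feat]] <<- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                                        adjust = "tukey"))
    }
    data.frame(feature = feat, ancova_F = F_g, ancova_p = p_g,
               partial_eta_sq = ss_g / (ss_g + ss_res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ancova_table", "data.frame")
  attr(out, "tukey") <- tukey
  attr(out, "covariates") <- names(covars)
  attr(out, "ss_type") <- ss_type
  out
}

#' Side-adjusted ANCOVA
#'
#' As [ancova_adjust()] with the affected/operated side classification
#' (`side_category`) dummy-coded among the covariates, to control for
#' population heterogeneity from unilateral versus bilateral involvement.
#' Side categories with a single subject are merged into the most frequent
#' category with a warning.
#'
#' @inheritParams ancova_adjust
#' @param extra_covariates additional covariates besides `side_category`
#'   (default none).
#' @return an `ancova_table` (see [ancova_adjust()]).
#' @export
side_adjusted_ancova <- function(fm, extra_covariates = character(),
                                 ss_type = c("II", "I", "III"), alpha = 0.05,
                                 columns = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!"side_category" %in% names(fm$covariates)) {
    stop("side_category covariate must be populated for every subject")
  }
  side <- as.character(fm$covariates$side_category)
  if (anyNA(side)) stop("side_category contains missing values")
  tab <- table(side)
  singletons <- names(tab)[tab == 1L]
  if (length(singletons)) {
    target <- names(tab)[which.max(tab)]
    warning("side categories with a single subject merged into '", target,
            "': ", paste(singletons, collapse = ", "))
    side[side %in% singletons] <- target
  }
  fm$covariates$side_category <- factor(side)
  ancova_adjust(fm, covariates = c("side_category", extra_covariates),
                ss_type = ss_type, alpha = alpha, columns = columns)
}

#' Percent change between two group means
#'
#' `100 * (comparison - reference) / reference`, the signed percentage used
#' to summarize feature differences between groups (e.g. KOA relative to
#' Healthy). Reported to one decimal place by convention; the returned value
#' is unrounded.
#'
#' @param reference_mean reference group mean (nonzero).
#' @param comparison_mean comparison group mean.
#' @return signed percent change.
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(reference_mean == 0)) stop("reference mean must be nonzero")
  100 * (comparison_mean - reference_mean) / reference_mean
}

#' Mean and SD summary per group (report layout)
#'
#' @param fm a [feature_matrix()].
#' @param columns feature columns; defaults to all numeric.
#' @return data frame: feature, then `<group>_mean` and `<group>_sd` columns.
#' @export
group_summary <- function(fm, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(fm$features)[vapply(fm$features, is.numeric, logical(1))]
  }
  g <- fm$group
  out <- data.frame(feature = columns)
  for (lv in levels(g)) {
    sel <- g == lv
    out[[paste0(lv, "_mean")]] <- vapply(columns, function(f) mean(fm$features[[f]][sel], na.rm = TRUE), numeric(1))
    out[[paste0(lv, "_sd")]] <- vapply(columns, function(f) stats::sd(fm$features[[f]][sel], na.rm = TRUE), numeric(1))
  }
  out
}
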