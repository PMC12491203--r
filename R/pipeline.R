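# Pipeline orchestration: simulate -> extract -> stats -> classify -> report
# as composable functions sharing one validated configuration. Every report
# embeds the effective configuration and seed so any output is a pure
# function of (inputs, config, seed).

#' Default run configuration
#'
#' All tunable pipeline settings with their defaults: normalized cycle
#' length `n_cycle_points` (101), sample-entropy parameters (`sampen_m` 2,
#' `sampen_r_frac` 0.1, SD-relative tolerance, concatenated-cycle input),
#' event-detection settings, cycle-selection range (3-5), feature
#' aggregation, statistics options, and the CV/bootstrap settings.
#'
#' @param ... overrides for individual keys; unknown keys are rejected.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_cycle_points = 101L,
    onset_prominence_frac = 0.05,
    smooth_window = 5L,
    min_cycle_separation_frac = 0.5,
    trough_depth_frac = 0.35,
    k_min_cycles = 3L,
    k_max_cycles = 5L,
    aggregate = "mean",
    sampen_m = 2L,
    sampen_r_frac = 0.1,
    sampen_r_mode = "sd_relative",
    sampen_input = "concatenated",
    alpha = 0.05,
    pairwise_threshold = 0.017,
    ancova_covariates = c("age", "sex", "bmi"),
    ss_type = "II",
    models = c("rf", "svm", "dt", "knn"),
    rf_search = "random",
    k_outer = 5L,
    k_inner = 3L,
    top_k = 10L,
    bootstrap_B = 1000L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are a subset of [default_config()].
#' @return a `run_config` with file values layered over the defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Extract the feature matrix from a cohort
#'
#' Per subject: detect gait events on the ankle trace, segment and
#' time-normalize cycles, select 3-5 of them (seeded per subject), compute
#' the subject-level cyclogram features and joint sample entropies, and join
#' the spatiotemporal parameters and covariates from the metadata. Subjects
#' failing segmentation are excluded and listed in the `rejects` attribute,
#' never silently dropped.
#'
#' @param cohort a `gait_cohort` from [read_cohort()] or [generate_cohort()].
#' @param config a [default_config()].
#' @param seed seed for the per-subject cycle selection.
#' @return a [feature_matrix()] with attributes `rejects` (data frame of
#'   excluded subjects and reasons) and `config`.
#' @export
run_extract <- function(cohort, config = default_config(), seed = 1L) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rejects <- data.frame(subject_id = character(0), reason = character(0))
  rows <- list()
  for (i in seq_len(nrow(cohort$meta))) {
    sid <- cohort$meta$subject_id[i]
    trial <- cohort$trials[[sid]]
    feats <- tryCatch({
      cycles <- segment_cycles(
        trial, n_points = config$n_cycle_points,
        onset_prominence_frac = config$onset_prominence_frac,
        smooth_window = config$smooth_window,
        min_cycle_separation_frac = config$min_cycle_separation_frac,
        trough_depth_frac = config$trough_depth_frac)
      cycles <- select_cycles(cycles, config$k_min_cycles, config$k_max_cycles,
                              rng_seed = seed + i, subject_id = sid)
      c(aggregate_features(cycles, combine = config$aggregate),
        joint_entropies(cycles, m = config$sampen_m,
                        r_frac = config$sampen_r_frac,
                        r_mode = config$sampen_r_mode,
                        input = config$sampen_input))
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      rejects <- rbind(rejects, data.frame(subject_id = sid,
                                           reason = conditionMessage(feats)))
      next
    }
    rows[[sid]] <- feats
  }
  if (length(rows) == 0L) stop("no subject passed feature extraction")
  keep <- cohort$meta$subject_id %in% names(rows)
  meta <- cohort$meta[keep, , drop = FALSE]
  feat_df <- as.data.frame(do.call(rbind, rows[meta$subject_id]))
  sp_cols <- intersect(SPATIOTEMPORAL_FEATURES, names(meta))
  feat_df[sp_cols] <- meta[sp_cols]
  cov_cols <- intersect(COVARIATE_COLUMNS, names(meta))
  fm <- feature_matrix(meta$subject_id, meta$group, feat_df,
                       covariates = if (length(cov_cols)) meta[cov_cols] else NULL)
  attr(fm, "rejects") <- rejects
  attr(fm, "config") <- config
  fm
}

#' Run the statistics protocol on a feature matrix
#'
#' Group summary (mean and SD per group), the nonparametric comparison
#' ([compare_groups()]), covariate-adjusted ANCOVA ([ancova_adjust()]), and
#' the side-adjusted ANCOVA ([side_adjusted_ancova()]) when `side_category`
#' is available.
#'
#' @param fm a [feature_matrix()].
#' @param config a [default_config()].
#' @return list of class `stats_report`.
#' @export
run_stats <- function(fm, config = default_config()) {
  side <- if (!is.null(fm$covariates) && "side_category" %in% names(fm$covariates) &&
              !anyNA(fm$covariates$side_category)) {
    side_adjusted_ancova(fm, ss_type = config$ss_type, alpha = config$alpha)
  } else NULL
  structure(list(
    summary = group_summary(fm),
    comparison = compare_groups(fm, alpha = config$alpha,
                                pairwise_threshold = config$pairwise_threshold),
    ancova = ancova_adjust(fm, covariates = config$ancova_covariates,
                           ss_type = config$ss_type, alpha = config$alpha),
    side_ancova = side,
    config = config
  ), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Statistics report:", nrow(x$comparison), "features compared\n")
  sig <- x$comparison$feature[x$comparison$kw_p < attr(x$comparison, "alpha")]
  cat("  omnibus-significant:", if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Run the classification evaluation
#'
#' Nested stratified CV of every configured model on every feature set,
#' bootstrap AUC intervals, top-5 feature importances per (model, fused)
#' fit, and the LDA baseline on the fused and spatiotemporal sets.
#'
#' @param fm a [feature_matrix()].
#' @param config a [default_config()].
#' @param seed master seed; the full report is reproducible from it.
#' @return list of class `cv_report` with `table` (one row per model and
#'   feature set), `results` (the `cv_result` objects), `auc_ci`,
#'   `importances`, `lda`, `seed`, `config`.
#' @export
run_classify <- function(fm, config = default_config(), seed = 1L) {
  views <- assemble_feature_sets(fm)
  grids <- default_grids(config$rf_search)
  y <- fm$group
  results <- list(); auc_ci <- list(); tab <- list()
  for (vw in names(views)) {
    for (mdl in config$models) {
      key <- paste(mdl, vw, sep = ".")
      cv <- nested_cv_evaluate(views[[vw]], y, mdl, seed = seed, grids = grids,
                               k_outer = config$k_outer, k_inner = config$k_inner,
                               top_k = config$top_k)
      bs <- bootstrap_auc(cv, B = config$bootstrap_B, seed = seed)
      results[[key]] <- cv
      auc_ci[[key]] <- bs
      tab[[key]] <- data.frame(model = toupper(mdl), feature_set = vw,
                               accuracy = cv$metrics[["accuracy"]],
                               precision = cv$metrics[["precision"]],
                               recall = cv$metrics[["recall"]],
                               f1 = cv$metrics[["f1"]],
                               macro_auc = cv$metrics[["auc"]],
                               auc_ci_lo = bs$ci[1], auc_ci_hi = bs$ci[2])
    }
  }
  importances <- lapply(stats::setNames(config$models, config$models), function(mdl) {
    pp <- preprocess_fold(views$fused)
    fit <- fit_classifier(mdl, pp$train, y, seed = seed)
    compute_importances(fit, pp$train, y, seed = seed)
  })
  lda <- c(fused = lda_baseline(views$fused, y, seed = seed),
           spatiotemporal = lda_baseline(views$spatiotemporal, y, seed = seed))
  table <- do.call(rbind, tab)
  rownames(table) <- NULL
  structure(list(table = table, results = results, auc_ci = auc_ci,
                 importances = importances, lda = lda, seed = seed,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested-CV classification report (seed", x$seed, ")\n")
  tbl <- x$table
  tbl[3:8] <- lapply(tbl[3:8], round, 2)
  print(tbl, row.names = FALSE)
  cat(sprintf("LDA baseline: fused %.1f%% vs spatiotemporal %.1f%%\n",
              x$lda["fused"], x$lda["spatiotemporal"]))
  invisible(x)
}

#' Run the full pipeline and write a report bundle
#'
#' simulate -> extract -> stats -> classify, written to `out_dir` as CSV and
#' JSON artifacts plus a manifest with a content hash per output. Stage
#' failures mark the bundle partial instead of aborting it.
#'
#' @param spec a [cohort_spec()].
#' @param config a [default_config()].
#' @param seed master seed for every stage.
#' @param out_dir output directory.
#' @return list with the in-memory stage outputs and the manifest;
#'   `partial` is `TRUE` when a stage failed (its error is in `errors`).
#' @export
run_all <- function(spec = cohort_spec(), config = default_config(), seed = 1L,
                    out_dir = tempfile("gaitfusion_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  cohort <- stage("simulate", generate_cohort(spec, seed = seed,
                                              dir = file.path(out_dir, "cohort")))
  fm <- if (!is.null(cohort)) stage("extract", {
    out <- run_extract(cohort, config, seed = seed)
    write_feature_matrix(out, file.path(out_dir, "feature_matrix.csv"))
    rej <- attr(out, "rejects")
    if (nrow(rej)) .write_csv(rej, file.path(out_dir, "rejects.csv"))
    out
  })
  stats_rep <- if (!is.null(fm)) stage("stats", {
    rep <- run_stats(fm, config)
    .write_csv(rep$summary, file.path(out_dir, "group_summary.csv"))
    .write_csv(as.data.frame(rep$comparison), file.path(out_dir, "group_comparison.csv"))
    .write_csv(as.data.frame(rep$ancova), file.path(out_dir, "ancova.csv"))
    if (!is.null(rep$side_ancova)) {
      .write_csv(as.data.frame(rep$side_ancova), file.path(out_dir, "ancova_side.csv"))
    }
    rep
  })
  cv_rep <- if (!is.null(fm)) stage("classify", {
    rep <- run_classify(fm, config, seed = seed)
    .write_csv(rep$table, file.path(out_dir, "cv_table.csv"))
    jsonlite::write_json(list(seed = seed, config = unclass(config),
                              lda = as.list(rep$lda),
                              table = rep$table),
                         file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(seed = seed, config = unclass(config),
                   partial = length(errors) > 0, errors = errors,
                   outputs = lapply(stats::setNames(files, sub(paste0(out_dir, "/"), "", files)),
                                    function(f) as.character(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(cohort = cohort, feature_matrix = fm, stats = stats_rep,
       classification = cv_rep, manifest = manifest, out_dir = out_dir,
       partial = length(errors) > 0, errors = errors)
}
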