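# On-disk formats: comma-separated UTF-8 text with a mandatory header row and
# "." as the decimal mark. Angle sign convention: flexion positive; for the
# ankle, dorsiflexion positive and plantarflexion negative. Event detection
# relies on this convention (toe-off = plantarflexion minimum).

GROUP_LEVELS <- c("Healthy", "KOA", "TKA")
SIDE_LEVELS <- c("unilateral_left", "unilateral_right", "bilateral", "none")
JOINTS <- c("hip", "knee", "ankle")

CYCLOGRAM_FEATURES <- c("hip_rom", "knee_rom", "hip_com", "knee_com",
                        "perimeter_stance", "perimeter_swing", "perimeter_total",
                        "area_stance", "area_swing", "area_total")
ENTROPY_FEATURES <- c("se_hip", "se_knee", "se_ankle")
SPATIOTEMPORAL_FEATURES <- c("speed", "stride_length", "stride_width",
                             "step_length_left", "step_length_right")
COVARIATE_COLUMNS <- c("age", "sex", "bmi", "side_category")

#' Canonical feature-to-category map
#'
#' Names every feature the pipeline emits and tags it with its category:
#' `cyclogram` (hip-knee cyclogram morphology), `entropy` (sample entropy of
#' joint-angle sequences), or `spatiotemporal` (traditional gait parameters).
#' The fused feature set used by the classifiers is cyclogram + entropy.
#'
#' @return named character vector mapping feature name to category.
#' @export
feature_categories <- function() {
  c(stats::setNames(rep("cyclogram", length(CYCLOGRAM_FEATURES)), CYCLOGRAM_FEATURES),
    stats::setNames(rep("entropy", length(ENTROPY_FEATURES)), ENTROPY_FEATURES),
    stats::setNames(rep("spatiotemporal", length(SPATIOTEMPORAL_FEATURES)),
                    SPATIOTEMPORAL_FEATURES))
}

#' Construct a trial recording
#'
#' One walking trial for one subject: hip, knee, and ankle flexion-angle
#' traces (degrees), uniformly sampled at `sampling_rate` Hz, equal lengths.
#'
#' @param subject_id subject identifier.
#' @param hip,knee,ankle numeric angle traces in degrees (equal length).
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param side recorded side, `"left"` or `"right"`.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, hip, knee, ankle, sampling_rate = 100,
                            side = "left") {
  n <- length(hip)
  if (length(knee) != n || length(ankle) != n) {
    stop("hip, knee, and ankle traces must have equal length")
  }
  if (!all(is.finite(hip), is.finite(knee), is.finite(ankle))) {
    stop("angle traces must be finite")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (Hz)")
  }
  side <- match.arg(side, c("left", "right"))
  structure(list(subject_id = as.character(subject_id), side = side,
                 sampling_rate = sampling_rate,
                 angles = data.frame(hip = as.numeric(hip),
                                     knee = as.numeric(knee),
                                     ankle = as.numeric(ankle))),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("Trial recording for subject", x$subject_id, "(", x$side, "side):",
      nrow(x$angles), "samples at", x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Read one joint-angle trial file
#'
#' Reads a delimited text trial (header row, comma-separated, degrees) and
#' validates it into a [trial_recording()]. Row order is preserved as time
#' order. Column names are remappable through `schema`.
#'
#' @param path path to the trial CSV.
#' @param schema named character vector mapping the joints `hip`, `knee`,
#'   `ankle` (and optionally `time`) to column names in the file.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param side,sampling_rate see [trial_recording()]. If the schema names a
#'   time column and `sampling_rate` is `NULL`, the rate is inferred from the
#'   median sampling interval.
#' @return a `trial_recording`.
#' @export
read_trial <- function(path,
                       schema = c(time = "time_s", hip = "hip_deg",
                                  knee = "knee_deg", ankle = "ankle_deg"),
                       subject_id = NULL, side = "left", sampling_rate = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, blank.lines.skip = TRUE,
                        strip.white = TRUE, colClasses = "character")
  missing_joints <- JOINTS[!schema[JOINTS] %in% names(df)]
  if (length(missing_joints)) {
    stop("trial file ", path, " is missing required column(s): ",
         paste(schema[missing_joints], collapse = ", "))
  }
  parse_col <- function(joint) {
    raw <- df[[schema[[joint]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(raw))
    if (length(bad)) {
      stop("non-numeric value in column '", schema[[joint]], "' of ", path,
           " at data row ", bad[1L], ": '", raw[bad[1L]], "'")
    }
    if (anyNA(val)) {
      stop("missing angle value in column '", schema[[joint]], "' of ", path,
           " at data row ", which(is.na(val))[1L])
    }
    val
  }
  hip <- parse_col("hip"); knee <- parse_col("knee"); ankle <- parse_col("ankle")
  if (is.null(sampling_rate)) {
    if (!is.na(schema["time"]) && schema[["time"]] %in% names(df)) {
      tm <- suppressWarnings(as.numeric(df[[schema[["time"]]]]))
      dt <- stats::median(diff(tm))
      if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time column in ", path)
      sampling_rate <- 1 / dt
    } else {
      sampling_rate <- 100
    }
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  trial_recording(subject_id, hip, knee, ankle,
                  sampling_rate = sampling_rate, side = side)
}

#' Write a trial recording to a CSV file
#'
#' Inverse of [read_trial()]: writes `time_s`, `hip_deg`, `knee_deg`,
#' `ankle_deg` columns at full precision so that a read-back reproduces the
#' trial exactly.
#'
#' @param trial a [trial_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- nrow(trial$angles)
  df <- data.frame(time_s = (seq_len(n) - 1L) / trial$sampling_rate,
                   hip_deg = trial$angles$hip,
                   knee_deg = trial$angles$knee,
                   ankle_deg = trial$angles$ankle)
  .write_csv(df, path)
  invisible(path)
}

.write_csv <- function(df, path) {
  ok <- tryCatch({
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    # 17 significant digits round-trips doubles exactly
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
    })
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read subject metadata and trial files into a cohort
#'
#' Joins a metadata table (one row per subject) with per-subject trial files
#' named `<subject_id>.csv` in `trials_dir`. Subjects with no trial file are
#' never silently dropped: depending on `missing_trial` they either abort the
#' read or are excluded with a warning and listed in the result's
#' `rejects` attribute.
#'
#' @param meta_path CSV with columns `subject_id`, `group`, `age`, `sex`,
#'   `bmi`, `side_category`, and the spatiotemporal parameters `speed`,
#'   `stride_length`, `stride_width`, `step_length_left`, `step_length_right`
#'   (spatiotemporal cells may be empty; downstream imputation handles them).
#' @param trials_dir directory containing the trial CSVs.
#' @param missing_trial `"error"` (default) or `"warn"`.
#' @param schema passed to [read_trial()].
#' @return an object of class `gait_cohort`: list with `meta` (data frame,
#'   ordered by subject_id) and `trials` (named list of `trial_recording`).
#' @export
read_cohort <- function(meta_path, trials_dir, missing_trial = c("error", "warn"),
                        schema = c(time = "time_s", hip = "hip_deg",
                                   knee = "knee_deg", ankle = "ankle_deg")) {
  missing_trial <- match.arg(missing_trial)
  meta <- utils::read.csv(meta_path, check.names = FALSE, strip.white = TRUE,
                          blank.lines.skip = TRUE)
  required <- c("subject_id", "group")
  if (!all(required %in% names(meta))) {
    stop("metadata table must contain columns: ", paste(required, collapse = ", "))
  }
  meta$subject_id <- as.character(meta$subject_id)
  dup <- meta$subject_id[duplicated(meta$subject_id)]
  if (length(dup)) stop("duplicate subject_id in metadata: ", paste(unique(dup), collapse = ", "))
  bad_group <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  }
  meta <- meta[order(meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$group <- factor(meta$group, levels = GROUP_LEVELS)
  if ("side_category" %in% names(meta)) {
    bad_side <- setdiff(stats::na.omit(unique(meta$side_category)), SIDE_LEVELS)
    if (length(bad_side)) stop("unknown side_category: ", paste(bad_side, collapse = ", "))
  }

  paths <- file.path(trials_dir, paste0(meta$subject_id, ".csv"))
  have <- file.exists(paths)
  if (any(!have)) {
    msg <- paste0(sum(!have), " subject(s) have no trial file in ", trials_dir,
                  ": ", paste(meta$subject_id[!have], collapse = ", "))
    if (missing_trial == "error") stop(msg) else warning(msg)
  }
  trials <- stats::setNames(
    lapply(which(have), function(i) {
      read_trial(paths[i], schema = schema, subject_id = meta$subject_id[i])
    }),
    meta$subject_id[have])
  structure(list(meta = meta[have, , drop = FALSE], trials = trials),
            rejects = meta$subject_id[!have], class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("Gait cohort:", nrow(x$meta), "subjects (",
      paste(sprintf("%s=%d", levels(x$meta$group), table(x$meta$group)), collapse = ", "),
      ")\n")
  rej <- attr(x, "rejects")
  if (length(rej)) cat("  subjects without trials:", paste(rej, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a feature matrix
#'
#' Subjects-by-features table with category tags, group labels, and
#' covariates: the single interchange object between feature extraction, the
#' statistics protocol, and the machine-learning harness.
#'
#' @param subject_id character vector of unique subject ids.
#' @param group factor (or character) with levels Healthy/KOA/TKA.
#' @param features data frame of numeric feature columns.
#' @param covariates data frame of covariates (`age`, `sex`, `bmi`,
#'   `side_category`), or `NULL`.
#' @param categories named character vector tagging every feature column;
#'   defaults to [feature_categories()] for known names.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(subject_id, group, features, covariates = NULL,
                           categories = NULL) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject ids in feature matrix")
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (anyNA(group)) stop("group labels must be one of ", paste(GROUP_LEVELS, collapse = "/"))
  features <- as.data.frame(features)
  if (nrow(features) != length(subject_id)) stop("features must have one row per subject")
  if (is.null(categories)) {
    known <- feature_categories()
    categories <- known[names(features)]
    names(categories) <- names(features)
    categories[is.na(categories)] <- "other"
  }
  if (!all(names(features) %in% names(categories))) {
    stop("every feature column needs a category tag")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(subject_id)) stop("covariates must have one row per subject")
  }
  structure(list(subject_id = subject_id, group = group, features = features,
                 covariates = covariates,
                 categories = categories[names(features)]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", length(x$subject_id), "subjects x",
      ncol(x$features), "features\n")
  cat("  categories:", paste(sprintf("%s=%d", names(table(x$categories)),
                                     table(x$categories)), collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) c(length(x$subject_id), ncol(x$features))

#' Write a feature matrix to CSV
#'
#' One row per subject; columns are `subject_id`, `group`, the covariates,
#' then the feature columns in a deterministic order (cyclogram, entropy,
#' spatiotemporal, then any others, alphabetical within category). Values are
#' written at full precision so the read-back is exact.
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  ord <- order(match(fm$categories, c("cyclogram", "entropy", "spatiotemporal")),
               names(fm$features))
  feats <- fm$features[, ord, drop = FALSE]
  df <- data.frame(subject_id = fm$subject_id, group = as.character(fm$group),
                   stringsAsFactors = FALSE)
  if (!is.null(fm$covariates)) df <- cbind(df, fm$covariates)
  df <- cbind(df, feats)
  .write_csv(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param categories optional named character vector of category tags;
#'   defaults to the canonical [feature_categories()] map, with unknown
#'   columns tagged `"other"`.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path, categories = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE,
                        blank.lines.skip = TRUE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("feature matrix file must contain subject_id and group columns")
  }
  covar <- intersect(COVARIATE_COLUMNS, names(df))
  feat_cols <- setdiff(names(df), c("subject_id", "group", covar))
  feature_matrix(df$subject_id, df$group, df[feat_cols],
                 covariates = if (length(covar)) df[covar] else NULL,
                 categories = categories)
}
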