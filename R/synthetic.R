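# Seeded synthetic cohort generator. Each subject's joint-angle curves are
# built from a fixed smooth periodic basis over the gait-cycle phase u in
# [0, 1): the hip is a single flexion-extension wave, the knee a two-peak
# flexion wave (small stance flexion, large swing flexion), and the ankle a
# dorsiflexion plateau with a sharp plantarflexion trough at the drawn
# stance fraction (the toe-off landmark) and a narrow dorsiflexion apex at
# the cycle boundary (the heel-strike landmark). Low-pass-filtered Gaussian
# noise scaled to a fraction of each joint's range of motion is the
# "complexity" knob that raises sample entropy; after noise is added, each
# cycle's hip and knee curves are affinely mapped onto the drawn range of
# motion and centroid, so the manifest values are exact ground truth for
# recovery tests. Group means and SDs default to published cohort anchors
# for healthy, KOA, and post-TKA gait (see
# extdata/reference_group_means.csv); every value is configurable.

#' Reference group means and SDs for the gait features
#'
#' Published cohort anchors (mean and SD per group) for the ten cyclogram
#' features and three sample entropies, used both as generator defaults and
#' for percent-change summaries between group means.
#'
#' @return data frame with columns `feature`, `<group>_mean`, `<group>_sd`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "reference_group_means.csv", package = "gaitfusion")
  utils::read.csv(path, check.names = FALSE)
}

.ref_anchor <- function(ref, feature, group, what = "mean") {
  ref[ref$feature == feature, paste0(tolower(group), "_", what)]
}

#' Group profile for the synthetic generator
#'
#' @param group `"Healthy"`, `"KOA"`, or `"TKA"`.
#' @param n_subjects number of subjects.
#' @param hip_rom_mean,hip_rom_sd,knee_rom_mean,knee_rom_sd per-subject
#'   range-of-motion distribution (degrees); defaults are the group anchors.
#' @param hip_com_mean,hip_com_sd,knee_com_mean,knee_com_sd centroid (mean
#'   joint angle) distribution (degrees).
#' @param stance_fraction_mean,stance_fraction_sd stance-phase share of the
#'   cycle (defaults 0.60 and 0.012: stance is about 60% of the gait cycle).
#' @param complexity_noise_sd smoothed additive noise SD as a fraction of
#'   each joint's range of motion -- the knob that raises sample entropy.
#' @param cycle_jitter_sd per-cycle duration jitter in seconds.
#' @param speed,stride_length,stride_width,step_length_left,step_length_right
#'   two-element `c(mean, sd)` vectors for the spatiotemporal parameters
#'   (m/s and m).
#' @param age,bmi two-element `c(mean, sd)` covariate distributions.
#' @param side_probs named probabilities over the side categories.
#' @return list of class `group_profile`.
#' @export
group_profile <- function(group = c("Healthy", "KOA", "TKA"),
                          n_subjects = NULL,
                          hip_rom_mean = NULL, hip_rom_sd = NULL,
                          knee_rom_mean = NULL, knee_rom_sd = NULL,
                          hip_com_mean = NULL, hip_com_sd = NULL,
                          knee_com_mean = NULL, knee_com_sd = NULL,
                          stance_fraction_mean = 0.60, stance_fraction_sd = 0.012,
                          complexity_noise_sd = NULL, cycle_jitter_sd = 0.02,
                          speed = NULL, stride_length = NULL, stride_width = NULL,
                          step_length_left = NULL, step_length_right = NULL,
                          age = NULL, bmi = NULL, side_probs = NULL) {
  group <- match.arg(group)
  ref <- reference_group_means()
  a <- function(feat, what) .ref_anchor(ref, feat, group, what)
  defaults <- switch(group,
    Healthy = list(n = 21L, noise = 0.008, speed = c(1.15, 0.12),
                   stride = c(1.22, 0.10), width = c(0.105, 0.020),
                   stepl = c(0.61, 0.05), stepr = c(0.61, 0.05),
                   age = c(56.6, 13.8), bmi = c(25.1, 2.9),
                   side = c(none = 1)),
    KOA = list(n = 24L, noise = 0.021, speed = c(0.88, 0.14),
               stride = c(1.00, 0.11), width = c(0.115, 0.025),
               stepl = c(0.48, 0.06), stepr = c(0.52, 0.06),
               age = c(58.9, 11.4), bmi = c(26.0, 0.3),
               side = c(unilateral_left = 7, unilateral_right = 3, bilateral = 14) / 24),
    TKA = list(n = 25L, noise = 0.003, speed = c(0.92, 0.13),
               stride = c(1.03, 0.10), width = c(0.115, 0.020),
               stepl = c(0.50, 0.06), stepr = c(0.53, 0.06),
               age = c(65.2, 10.1), bmi = c(27.2, 3.5),
               side = c(unilateral_left = 11, unilateral_right = 9, bilateral = 5) / 25))
  prof <- list(
    group = group,
    n_subjects = n_subjects %||% defaults$n,
    hip_rom_mean = hip_rom_mean %||% a("hip_rom", "mean"),
    hip_rom_sd = hip_rom_sd %||% a("hip_rom", "sd"),
    knee_rom_mean = knee_rom_mean %||% a("knee_rom", "mean"),
    knee_rom_sd = knee_rom_sd %||% a("knee_rom", "sd"),
    hip_com_mean = hip_com_mean %||% a("hip_com", "mean"),
    hip_com_sd = hip_com_sd %||% a("hip_com", "sd"),
    knee_com_mean = knee_com_mean %||% a("knee_com", "mean"),
    knee_com_sd = knee_com_sd %||% a("knee_com", "sd"),
    stance_fraction_mean = stance_fraction_mean,
    stance_fraction_sd = stance_fraction_sd,
    complexity_noise_sd = complexity_noise_sd %||% defaults$noise,
    cycle_jitter_sd = cycle_jitter_sd,
    speed = speed %||% defaults$speed,
    stride_length = stride_length %||% defaults$stride,
    stride_width = stride_width %||% defaults$width,
    step_length_left = step_length_left %||% defaults$stepl,
    step_length_right = step_length_right %||% defaults$stepr,
    age = age %||% defaults$age,
    bmi = bmi %||% defaults$bmi,
    side_probs = side_probs %||% defaults$side
  )
  stopifnot(prof$n_subjects >= 1L,
            prof$stance_fraction_mean > 0.4, prof$stance_fraction_mean < 0.8,
            prof$complexity_noise_sd >= 0, prof$cycle_jitter_sd >= 0)
  structure(prof, class = "group_profile")
}

#' Cohort specification for the synthetic generator
#'
#' @param profiles list of three [group_profile()]s (defaults: the
#'   Healthy/KOA/TKA anchors with group sizes 21/24/25).
#' @param sampling_rate sampling frequency in Hz (default 100).
#' @param cycles_range integer range of complete gait cycles per subject
#'   (default `c(3, 5)`, the acquisition convention).
#' @param base_cycle_duration mean gait-cycle duration in seconds.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles = list(group_profile("Healthy"),
                                        group_profile("KOA"),
                                        group_profile("TKA")),
                        sampling_rate = 100, cycles_range = c(3L, 5L),
                        base_cycle_duration = 1.1) {
  structure(list(profiles = profiles, sampling_rate = sampling_rate,
                 cycles_range = as.integer(cycles_range),
                 base_cycle_duration = base_cycle_duration),
            class = "cohort_spec")
}

# wrapped Gaussian bump: periodic in u with period 1
.bump <- function(u, center, width) {
  d <- (u - center) %% 1
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

#' Draw one subject's gait-cycle template
#'
#' Draws the subject-level parameters from a [group_profile()] (using the
#' current RNG stream) and returns smooth periodic angle functions over the
#' normalized cycle phase `[0, 1)`, with `f(0) == f(1)` for every joint.
#' The ankle function takes the stance fraction as its second argument so
#' per-cycle stance variation can be injected.
#'
#' @param profile a [group_profile()].
#' @return list with functions `hip(u)`, `knee(u)`, `ankle(u, sf)` and the
#'   drawn `params`.
#' @export
generate_cycle_template <- function(profile) {
  rnorm_pos <- function(mean, sd, lo = 0.2 * mean) max(stats::rnorm(1, mean, sd), lo)
  params <- list(
    hip_rom = rnorm_pos(profile$hip_rom_mean, profile$hip_rom_sd),
    knee_rom = rnorm_pos(profile$knee_rom_mean, profile$knee_rom_sd),
    hip_com = stats::rnorm(1, profile$hip_com_mean, profile$hip_com_sd),
    knee_com = stats::rnorm(1, profile$knee_com_mean, profile$knee_com_sd),
    stance_fraction = min(max(stats::rnorm(1, profile$stance_fraction_mean,
                                           profile$stance_fraction_sd), 0.5), 0.7),
    noise_sd = max(stats::rnorm(1, profile$complexity_noise_sd,
                                0.1 * profile$complexity_noise_sd), 0)
  )
  hip <- function(u) params$hip_com + (params$hip_rom / 2) * cos(2 * pi * u)
  knee_raw <- function(u) 0.25 * .bump(u, 0.15, 0.06) + .bump(u, 0.72, 0.10)
  kr <- knee_raw(seq(0, 1, length.out = 2001)[-2001])
  k_scale <- params$knee_rom / diff(range(kr))
  k_shift <- params$knee_com - mean(kr) * k_scale
  knee <- function(u) k_shift + k_scale * knee_raw(u)
  ankle <- function(u, sf = params$stance_fraction) {
    6 * .bump(u, 0, 0.03) + 8 * .bump(u, 0.42, 0.10) -
      22 * .bump(u, sf, 0.035) + 2 * cos(2 * pi * u)
  }
  list(hip = hip, knee = knee, ankle = ankle, params = params)
}

# smoothed (moving average width 3) Gaussian noise
.smooth_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  .moving_average(stats::rnorm(n, 0, sd), 3L)
}

# affine map onto target range-of-motion and mean
.impose_rom_com <- function(x, rom, com) {
  rng <- diff(range(x))
  if (rng < 1e-12) return(rep(com, length(x)))
  com + (x - mean(x)) * (rom / rng)
}

#' Generate one synthetic subject
#'
#' Draws a cycle template, evaluates it over 3-5 gait cycles with per-cycle
#' duration and stance-fraction jitter plus a quarter-cycle lead-in and
#' tail, adds smoothed complexity noise, and imposes the drawn hip/knee
#' range of motion and centroid on every cycle. Uses the current RNG stream.
#'
#' @param profile a [group_profile()].
#' @param spec a [cohort_spec()].
#' @param subject_id identifier for the generated subject.
#' @return list with `meta` (one-row data frame), `trial`
#'   ([trial_recording()]), and `truth` (drawn parameters plus ground-truth
#'   event indices).
#' @export
generate_subject <- function(profile, spec, subject_id) {
  fs <- spec$sampling_rate
  tpl <- generate_cycle_template(profile)
  p <- tpl$params
  n_cycles <- sample(seq(spec$cycles_range[1], spec$cycles_range[2]), 1L)
  base_dur <- stats::rnorm(1, spec$base_cycle_duration, 0.05)
  durs <- pmax(stats::rnorm(n_cycles, base_dur, profile$cycle_jitter_sd), 0.6)
  n_k <- pmax(round(durs * fs), 60L)
  sf_k <- pmin(pmax(stats::rnorm(n_cycles, p$stance_fraction, 0.004), 0.5), 0.7)

  lead_len <- round(0.25 * n_k[1])
  tail_len <- round(0.25 * n_k[n_cycles])
  phases <- c((seq_len(lead_len) - lead_len - 1) / n_k[1],
              unlist(lapply(seq_len(n_cycles), function(k) (seq_len(n_k[k]) - 1) / n_k[k])),
              (seq_len(tail_len) - 1) / n_k[n_cycles])
  phases <- phases %% 1
  seg_id <- c(rep(0L, lead_len), rep(seq_len(n_cycles), n_k), rep(n_cycles + 1L, tail_len))
  sf_of <- c(sf_k[1], sf_k, sf_k[n_cycles])[seg_id + 1L]

  hip <- tpl$hip(phases)
  knee <- tpl$knee(phases)
  ankle <- tpl$ankle(phases, sf_of)
  hip <- hip + .smooth_noise(length(hip), p$noise_sd * p$hip_rom)
  knee <- knee + .smooth_noise(length(knee), p$noise_sd * p$knee_rom)
  ankle <- ankle + .smooth_noise(length(ankle), p$noise_sd * diff(range(ankle)))

  starts <- lead_len + c(0L, cumsum(n_k)) + 1L  # heel strikes (n_cycles + 1)
  for (k in seq_len(n_cycles)) {
    idx <- starts[k]:(starts[k + 1L] - 1L)
    hip[idx] <- .impose_rom_com(hip[idx], p$hip_rom, p$hip_com)
    knee[idx] <- .impose_rom_com(knee[idx], p$knee_rom, p$knee_com)
  }
  toe_off <- starts[seq_len(n_cycles)] + round(sf_k * n_k)

  side_cat <- sample(names(profile$side_probs), 1L, prob = profile$side_probs)
  draw2 <- function(v, lo = 0.01) max(stats::rnorm(1, v[1], v[2]), lo)
  meta <- data.frame(
    subject_id = subject_id, group = profile$group,
    age = round(min(max(stats::rnorm(1, profile$age[1], profile$age[2]), 35), 88)),
    sex = sample(c("F", "M"), 1L),
    bmi = round(min(max(stats::rnorm(1, profile$bmi[1], profile$bmi[2]), 17), 40), 1),
    side_category = side_cat,
    speed = draw2(profile$speed), stride_length = draw2(profile$stride_length),
    stride_width = draw2(profile$stride_width),
    step_length_left = draw2(profile$step_length_left),
    step_length_right = draw2(profile$step_length_right))
  trial <- trial_recording(subject_id, hip, knee, ankle, sampling_rate = fs,
                           side = sample(c("left", "right"), 1L))
  truth <- c(p, list(n_cycles = n_cycles, heel_strikes = starts,
                     toe_offs = toe_off, stance_fractions = sf_k,
                     cycle_samples = n_k))
  list(meta = meta, trial = trial, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()] (default: 21 Healthy, 24 KOA, 25 TKA
#'   subjects).
#' @param seed master seed; the whole cohort, including any files written,
#'   is reproducible from it.
#' @param dir optional output directory: writes `meta.csv`, a `trials/`
#'   directory of per-subject angle CSVs, and `manifest.csv` of drawn
#'   ground-truth parameters.
#' @return a `gait_cohort` (see [read_cohort()]) with attributes `manifest`
#'   (data frame of drawn parameters per subject) and `truth` (named list of
#'   ground-truth event indices and parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L, dir = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  metas <- list(); trials <- list(); truths <- list()
  idx <- 0L
  for (prof in spec$profiles) {
    for (s in seq_len(prof$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      sub <- generate_subject(prof, spec, sid)
      metas[[sid]] <- sub$meta
      trials[[sid]] <- sub$trial
      truths[[sid]] <- sub$truth
    }
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  meta$group <- factor(meta$group, levels = GROUP_LEVELS)
  manifest <- do.call(rbind, lapply(names(truths), function(sid) {
    tr <- truths[[sid]]
    data.frame(subject_id = sid, group = as.character(meta$group[meta$subject_id == sid]),
               hip_rom = tr$hip_rom, knee_rom = tr$knee_rom,
               hip_com = tr$hip_com, knee_com = tr$knee_com,
               stance_fraction = tr$stance_fraction, noise_sd = tr$noise_sd,
               n_cycles = tr$n_cycles)
  }))
  cohort <- structure(list(meta = meta, trials = trials),
                      rejects = character(0), class = "gait_cohort")
  attr(cohort, "manifest") <- manifest
  attr(cohort, "truth") <- truths
  attr(cohort, "seed") <- seed
  if (!is.null(dir)) {
    dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
    .write_csv(meta, file.path(dir, "meta.csv"))
    .write_csv(manifest, file.path(dir, "manifest.csv"))
    for (sid in names(trials)) {
      write_trial(trials[[sid]], file.path(dir, "trials", paste0(sid, ".csv")))
    }
  }
  cohort
}
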