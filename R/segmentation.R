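# Gait events are read off the ankle flexion trace (dorsiflexion positive,
# plantarflexion negative): toe-off is the maximum plantarflexion angle, i.e.
# the deep minimum of the trace; heel strike is the onset of ankle-angle
# change after swing. "Onset" has no numeric definition in the clinical
# convention, so it is operationalized here as the first zero crossing
# (positive to non-positive) of the smoothed first difference following a
# toe-off minimum whose subsequent descent exceeds a prominence floor -- in
# late swing the ankle dorsiflexes back towards neutral and plateaus at a
# local maximum immediately before foot contact, and that turning point is
# taken as heel strike. The prominence floor and smoothing width are
# configurable; smoothing is applied only inside event detection, never to
# exported angles.

.moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  na <- is.na(sm)
  sm[na] <- x[na]  # edges keep raw values
  sm
}

#' Detect heel-strike and toe-off events from an ankle-angle trace
#'
#' @param ankle numeric ankle flexion trace in degrees (dorsiflexion
#'   positive, plantarflexion negative).
#' @param sampling_rate sampling frequency in Hz.
#' @param onset_prominence_frac heel-strike prominence floor as a fraction of
#'   the trace's range of motion (default 0.05): the descent following a
#'   candidate turning point must exceed this for the point to count as heel
#'   strike.
#' @param smooth_window moving-average width (samples) used only inside
#'   detection (default 5).
#' @param min_cycle_separation_frac minimum separation between toe-off
#'   minima, as a fraction of the median candidate spacing (default 0.5);
#'   suppresses double troughs.
#' @param trough_depth_frac only minima within this fraction of the range of
#'   motion above the global minimum are toe-off candidates (default 0.35).
#' @return data frame with columns `kind` (`"heel_strike"`/`"toe_off"`),
#'   `sample_index`, and `time_s`, strictly ordered and alternating.
#' @export
detect_events <- function(ankle, sampling_rate = 100,
                          onset_prominence_frac = 0.05,
                          smooth_window = 5L,
                          min_cycle_separation_frac = 0.5,
                          trough_depth_frac = 0.35) {
  if (!all(is.finite(ankle))) stop("ankle trace must be finite")
  n <- length(ankle)
  rom <- diff(range(ankle))
  if (n < 10L || rom < 1e-8) {
    stop("ankle trace is constant or too short: no gait events detectable")
  }
  s <- .moving_average(ankle, smooth_window)

  # toe-off: deep local minima (maximum plantarflexion)
  interior <- 2:(n - 1L)
  is_min <- s[interior] < s[interior - 1L] & s[interior] <= s[interior + 1L]
  cand <- interior[is_min]
  cand <- cand[s[cand] <= min(s) + trough_depth_frac * diff(range(s))]
  if (length(cand) == 0L) stop("no plantarflexion minima found: fewer than one complete gait cycle")
  if (length(cand) > 1L) {
    min_sep <- min_cycle_separation_frac * stats::median(diff(cand))
    keep <- cand[1L]
    for (i in cand[-1L]) {
      if (i - keep[length(keep)] < min_sep) {
        if (s[i] < s[keep[length(keep)]]) keep[length(keep)] <- i  # deeper trough wins
      } else keep <- c(keep, i)
    }
    cand <- keep
  }
  toe_off <- cand

  # heel strike: first sustained + -> <=0 zero crossing of the smoothed first
  # difference after each toe-off (and, if present, before the first one)
  d <- diff(s)
  prom <- onset_prominence_frac * diff(range(s))
  lookahead <- max(5L, as.integer(0.25 * stats::median(diff(c(0L, toe_off)))))
  find_onset <- function(from, to) {
    i <- from
    while (i < to - 1L) {
      if (d[i] > 0 && d[i + 1L] <= 0) {
        j <- (i + 2L):min(i + 1L + lookahead, n)
        # sustained descent: drops by the prominence floor and does not
        # rebound above the turning point within the lookahead (noise dips
        # on the swing-phase rise rebound towards the true maximum)
        if (s[i + 1L] - min(s[j]) >= prom && max(s[j]) <= s[i + 1L] + 0.25 * prom) {
          return(i + 1L)
        }
      }
      i <- i + 1L
    }
    NA_integer_
  }
  windows <- cbind(from = toe_off, to = c(toe_off[-1L], n))
  heel <- vapply(seq_len(nrow(windows)),
                 function(k) find_onset(windows[k, 1L], windows[k, 2L]),
                 integer(1))
  first <- if (toe_off[1L] > 3L) find_onset(1L, toe_off[1L]) else NA_integer_
  heel <- c(first, heel)
  heel <- heel[!is.na(heel)]
  if (length(heel) == 0L) stop("no heel-strike onsets found")

  ev <- rbind(data.frame(kind = "heel_strike", sample_index = heel),
              data.frame(kind = "toe_off", sample_index = toe_off))
  ev <- ev[order(ev$sample_index), , drop = FALSE]
  # enforce strict alternation: within a run of equal kinds keep the first
  keep <- c(TRUE, ev$kind[-1L] != ev$kind[-nrow(ev)])
  ev <- ev[keep, , drop = FALSE]
  ev$time_s <- (ev$sample_index - 1L) / sampling_rate
  rownames(ev) <- NULL
  ev
}

#' Cut a trial into time-normalized gait cycles
#'
#' One cycle per consecutive heel-strike pair containing exactly one toe-off;
#' all three joint traces are resampled to `n_points` with a not-a-knot cubic
#' spline ([resample_to_cycle()]). Cycles whose toe-off is missing or
#' ill-placed are skipped with a warning, never a crash.
#'
#' @param trial a [trial_recording()].
#' @param events event table from [detect_events()]; detected from the
#'   trial's ankle trace if omitted.
#' @param n_points normalized cycle length (default 101, i.e. 0-100% of the
#'   gait cycle in 1% steps).
#' @param ... detection settings forwarded to [detect_events()].
#' @return list of `gait_cycle` objects, each with `start_index`,
#'   `toe_off_index`, `end_index`, `stance_fraction`, and normalized `hip`,
#'   `knee`, `ankle` arrays of length `n_points`.
#' @export
segment_cycles <- function(trial, events = NULL, n_points = 101L, ...) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(events)) {
    events <- detect_events(trial$angles$ankle, trial$sampling_rate, ...)
  }
  hs <- events$sample_index[events$kind == "heel_strike"]
  to <- events$sample_index[events$kind == "toe_off"]
  if (length(hs) < 2L) stop("need at least 2 heel strikes to form a gait cycle")
  cycles <- list()
  for (k in seq_len(length(hs) - 1L)) {
    a <- hs[k]; b <- hs[k + 1L]
    t_in <- to[to > a & to < b]
    if (length(t_in) != 1L) {
      warning("cycle ", k, " (samples ", a, "-", b, ") skipped: ",
              length(t_in), " toe-off events inside")
      next
    }
    idx <- a:b
    cyc <- structure(list(
      start_index = a, toe_off_index = t_in, end_index = b,
      stance_fraction = (t_in - a) / (b - a),
      n_points = as.integer(n_points),
      hip = resample_to_cycle(trial$angles$hip[idx], n_points = n_points),
      knee = resample_to_cycle(trial$angles$knee[idx], n_points = n_points),
      ankle = resample_to_cycle(trial$angles$ankle[idx], n_points = n_points)
    ), class = "gait_cycle")
    cycles[[length(cycles) + 1L]] <- cyc
  }
  if (length(cycles) == 0L) stop("no valid gait cycles after segmentation")
  cycles
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("Gait cycle: samples %d-%d (toe-off %d, stance %.1f%%), %d normalized points\n",
              x$start_index, x$end_index, x$toe_off_index,
              100 * x$stance_fraction, x$n_points))
  invisible(x)
}

#' Randomly select gait cycles for feature extraction
#'
#' Emulates the acquisition protocol of keeping 3-5 complete gait cycles per
#' subject: draws a uniform random subset of size `min(k_max, available)`,
#' reproducibly under `rng_seed`, preserving time order.
#'
#' @param cycles list of `gait_cycle` objects.
#' @param k_min minimum acceptable number of cycles (default 3).
#' @param k_max maximum number kept (default 5).
#' @param rng_seed integer seed for the draw.
#' @param subject_id used in the error message when too few cycles exist.
#' @return sublist of `cycles`, in time order.
#' @export
select_cycles <- function(cycles, k_min = 3L, k_max = 5L, rng_seed = 1L,
                          subject_id = "?") {
  n <- length(cycles)
  if (n < k_min) {
    stop("subject ", subject_id, " has only ", n, " gait cycle(s); at least ",
         k_min, " required")
  }
  k <- min(k_max, n)
  if (k == n) return(cycles)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  pick <- sort(sample.int(n, k))
  cycles[pick]
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
}
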