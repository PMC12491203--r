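# Sample entropy (SampEn) of a joint-angle sequence: the negative natural
# logarithm of the conditional probability that two subsequences matching for
# m samples (within tolerance r, Chebyshev distance, self-matches excluded)
# also match for m+1 samples. Higher values mean a less regular, more complex
# signal. Template counts follow the standard formulation: both lengths use
# the same N - m template start positions, so the m+1 count can never exceed
# the m count and SampEn is non-negative.

#' Sample entropy of a numeric series
#'
#' @param series numeric vector (joint angles in degrees), length `N` with
#'   `N > m + 1`.
#' @param m embedding dimension (template length), default 2.
#' @param r_frac similarity tolerance; with `r_mode = "sd_relative"`
#'   (default) the tolerance is `r_frac * sd(series)`, the convention that
#'   adapts the tolerance to the dynamic range of the data. With
#'   `r_mode = "absolute"`, `r_frac` is used directly in degrees.
#' @param r_mode `"sd_relative"` or `"absolute"`.
#' @return sample entropy in nats (non-negative). A zero-variance series
#'   returns 0 with a warning (every template matches every other at both
#'   lengths). When no template pair matches at length `m + 1` the result is
#'   `Inf` with attribute `reason = "no matches at length m+1"`.
#' @export
sample_entropy <- function(series, m = 2L, r_frac = 0.1,
                           r_mode = c("sd_relative", "absolute")) {
  r_mode <- match.arg(r_mode)
  x <- as.numeric(series)
  N <- length(x)
  if (!all(is.finite(x))) stop("series must be finite")
  if (m < 1L) stop("embedding dimension m must be >= 1")
  if (N <= m + 1L) stop("series length N = ", N, " must exceed m + 1 = ", m + 1L)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) {
    warning("zero-variance series: sample entropy defined as 0")
    return(0)
  }
  r <- if (r_mode == "sd_relative") r_frac * s else r_frac
  if (r <= 0) stop("tolerance must be positive")

  # Chebyshev template distances built up one lag at a time
  nt <- N - m                     # template start positions for both lengths
  idx <- seq_len(nt)
  D <- abs(outer(x[idx], x[idx], "-"))
  for (k in seq_len(m - 1L)) {
    D <- pmax(D, abs(outer(x[idx + k], x[idx + k], "-")))
  }
  count_m <- sum(D <= r) - nt     # exclude self-matches (ordered pairs)
  D1 <- pmax(D, abs(outer(x[idx + m], x[idx + m], "-")))
  count_m1 <- sum(D1 <= r) - nt
  if (count_m == 0L) {
    return(structure(Inf, reason = "no matches at length m"))
  }
  if (count_m1 == 0L) {
    return(structure(Inf, reason = "no matches at length m+1"))
  }
  -log(count_m1 / count_m)
}

#' Joint-angle sample entropies for one subject
#'
#' Concatenates the subject's selected, time-normalized gait cycles in time
#' order into one sequence per joint and computes [sample_entropy()] once on
#' each (the default). With `input = "per_cycle_mean"` the entropy is instead
#' computed per cycle and averaged.
#'
#' @param cycles nonempty list of `gait_cycle` objects.
#' @param m,r_frac,r_mode passed to [sample_entropy()].
#' @param input `"concatenated"` (default) or `"per_cycle_mean"`.
#' @return named numeric vector `c(se_hip, se_knee, se_ankle)` in nats.
#' @export
joint_entropies <- function(cycles, m = 2L, r_frac = 0.1,
                            r_mode = c("sd_relative", "absolute"),
                            input = c("concatenated", "per_cycle_mean")) {
  r_mode <- match.arg(r_mode)
  input <- match.arg(input)
  if (length(cycles) == 0L) stop("no cycles supplied")
  one <- function(joint) {
    if (input == "concatenated") {
      x <- unlist(lapply(cycles, `[[`, joint), use.names = FALSE)
      sample_entropy(x, m = m, r_frac = r_frac, r_mode = r_mode)
    } else {
      mean(vapply(cycles, function(cy) {
        sample_entropy(cy[[joint]], m = m, r_frac = r_frac, r_mode = r_mode)
      }, numeric(1)))
    }
  }
  c(se_hip = as.numeric(one("hip")),
    se_knee = as.numeric(one("knee")),
    se_ankle = as.numeric(one("ankle")))
}
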