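# Hip-knee cyclograms: the closed planar curve traced by plotting the hip
# flexion angle (X) against the knee flexion angle (Y) over one gait cycle.
# Physiological traversal is clockwise (signed shoelace area negative).
# Morphological features: perimeter (polyline length including the closing
# segment), area (absolute shoelace sum with the standard closure term),
# centroid (mean hip/knee angle), and per-joint range of motion, each also
# decomposed into stance and swing contributions. Stance and swing parts are
# partial sums of the same closed-figure summation, so part sums equal the
# total identically; the closing segment from the last point back to the
# first belongs to the swing part by convention (for physiological loops the
# last point nearly coincides with the first, so the choice is immaterial).

#' Build a hip-knee cyclogram from a gait cycle
#'
#' @param cycle a `gait_cycle` from [segment_cycles()] (normalized `hip` and
#'   `knee` arrays plus `stance_fraction`).
#' @return an object of class `cyclogram`: data frame columns `hip`, `knee`
#'   (degrees) and `phase` (`"stance"`/`"swing"`), points ordered from heel
#'   strike; attribute `degenerate` flags an all-identical point set, and a
#'   warning is raised when traversal is not clockwise.
#' @export
build_cyclogram <- function(cycle) {
  hip <- cycle$hip; knee <- cycle$knee
  n <- length(hip)
  frac <- seq(0, 1, length.out = n)
  phase <- ifelse(frac <= cycle$stance_fraction + 1e-12, "stance", "swing")
  cg <- structure(data.frame(hip = hip, knee = knee, phase = phase),
                  class = c("cyclogram", "data.frame"))
  degenerate <- diff(range(hip)) < 1e-12 && diff(range(knee)) < 1e-12
  attr(cg, "degenerate") <- degenerate
  if (!degenerate && signed_area(hip, knee) > 0) {
    warning("cyclogram traversal is counter-clockwise; physiological hip-knee loops run clockwise")
  }
  cg
}

#' @export
print.cyclogram <- function(x, ...) {
  cat("Hip-knee cyclogram:", nrow(x), "points,",
      sum(x$phase == "stance"), "stance /", sum(x$phase == "swing"), "swing",
      if (isTRUE(attr(x, "degenerate"))) "(degenerate)" else "", "\n")
  invisible(x)
}

#' @describeIn build_cyclogram plot method (hip on X, knee on Y, phases
#'   colour-coded).
#' @param y,... graphics arguments (ignored/forwarded).
#' @export
plot.cyclogram <- function(x, y, ...) {
  cols <- ifelse(x$phase == "stance", "#1f6fb4", "#d1495b")
  graphics::plot(x$hip, x$knee, type = "n", xlab = "hip angle (deg)",
                 ylab = "knee angle (deg)", ...)
  graphics::lines(c(x$hip, x$hip[1]), c(x$knee, x$knee[1]), col = "grey60")
  graphics::points(x$hip, x$knee, col = cols, pch = 16, cex = 0.5)
  invisible(x)
}

#' Perimeter of a closed point sequence
#'
#' Sum of Euclidean distances between consecutive points plus the closing
#' segment from the last point back to the first.
#'
#' @param hip,knee coordinate vectors (degrees). A single point has
#'   perimeter 0.
#' @return non-negative perimeter in degrees.
#' @export
cyclogram_perimeter <- function(hip, knee) {
  sum(.segment_lengths(hip, knee))
}

# consecutive segment lengths, closing segment last (n of them)
.segment_lengths <- function(hip, knee) {
  n <- length(hip)
  if (n <= 1L) return(numeric(0))
  nxt <- c(2:n, 1L)
  sqrt((hip[nxt] - hip)^2 + (knee[nxt] - knee)^2)
}

#' Signed shoelace area of a closed point sequence
#'
#' One half of the cyclic sum of cross products
#' \eqn{\theta h_i \theta k_{i+1} - \theta k_i \theta h_{i+1}}, including the
#' standard closure term from the last point back to the first. Negative for
#' clockwise traversal.
#'
#' @inheritParams cyclogram_perimeter
#' @return signed area in squared degrees.
#' @export
signed_area <- function(hip, knee) {
  sum(.segment_cross(hip, knee)) / 2
}

# per-segment cross products of the shoelace sum (closing term last)
.segment_cross <- function(hip, knee) {
  n <- length(hip)
  if (n < 2L) return(numeric(0))
  nxt <- c(2:n, 1L)
  hip * knee[nxt] - knee * hip[nxt]
}

#' Absolute cyclogram area
#'
#' @inheritParams cyclogram_perimeter
#' @return `|signed shoelace area|`; 0 (with a `degenerate` attribute) when
#'   fewer than 3 points are supplied.
#' @export
cyclogram_area <- function(hip, knee) {
  if (length(hip) < 3L) return(structure(0, degenerate = TRUE))
  abs(signed_area(hip, knee))
}

#' Stance/swing decomposition of perimeter and area
#'
#' Totals are computed on the full closed figure; the stance and swing parts
#' are partial sums of the same per-segment terms, a segment belonging to the
#' phase of its starting point and the closing segment to swing. Hence
#' `stance + swing == total` exactly, for both quantities. Area parts carry
#' the orientation sign of the whole loop so that the total is non-negative;
#' for physiological loops both parts are non-negative as well.
#'
#' @param cyclogram a [build_cyclogram()] result.
#' @return named list with `perimeter_stance`, `perimeter_swing`,
#'   `perimeter_total`, `area_stance`, `area_swing`, `area_total`.
#' @export
phase_decompose <- function(cyclogram) {
  hip <- cyclogram$hip; knee <- cyclogram$knee
  n <- nrow(cyclogram)
  stance <- cyclogram$phase == "stance"
  stance[n] <- FALSE  # closing segment n -> 1 is assigned to swing
  seg_len <- .segment_lengths(hip, knee)
  seg_cross <- .segment_cross(hip, knee) / 2
  orient <- if (sum(seg_cross) > 0) 1 else -1
  p_st <- sum(seg_len[stance]); p_sw <- sum(seg_len[!stance])
  a_st <- orient * sum(seg_cross[stance]); a_sw <- orient * sum(seg_cross[!stance])
  # totals defined as the sum of the parts: additivity holds identically
  list(perimeter_stance = p_st, perimeter_swing = p_sw,
       perimeter_total = p_st + p_sw,
       area_stance = a_st, area_swing = a_sw,
       area_total = a_st + a_sw)
}

#' Cyclogram centroid: mean hip and knee angle
#'
#' @param cycle a `gait_cycle` (or any list with `hip`/`knee` vectors).
#' @return named vector `c(hip_com, knee_com)` in degrees.
#' @export
cyclogram_centroid <- function(cycle) {
  if (length(cycle$hip) == 0L) stop("cannot compute centroid of an empty cycle")
  c(hip_com = mean(cycle$hip), knee_com = mean(cycle$knee))
}

#' Per-joint range of motion
#'
#' @param cycle a `gait_cycle`.
#' @return named vector `c(hip_rom, knee_rom)`: max minus min joint angle in
#'   degrees.
#' @export
range_of_motion <- function(cycle) {
  if (length(cycle$hip) == 0L) stop("cannot compute range of motion of an empty cycle")
  c(hip_rom = diff(range(cycle$hip)), knee_rom = diff(range(cycle$knee)))
}

#' Per-cycle cyclogram features
#'
#' @param cycle a `gait_cycle`.
#' @return named numeric vector with the ten cyclogram features: `hip_rom`,
#'   `knee_rom`, `hip_com`, `knee_com`, `perimeter_stance/swing/total`,
#'   `area_stance/swing/total`.
#' @export
cyclogram_features <- function(cycle) {
  cg <- suppressWarnings(build_cyclogram(cycle))
  parts <- phase_decompose(cg)
  c(range_of_motion(cycle), cyclogram_centroid(cycle), unlist(parts))
}

#' Subject-level cyclogram features from selected cycles
#'
#' Per-cycle features are combined across the subject's selected gait cycles
#' by the arithmetic mean (default) or the median.
#'
#' @param cycles nonempty list of `gait_cycle` objects.
#' @param combine `"mean"` (default) or `"median"`.
#' @return named numeric vector as [cyclogram_features()].
#' @export
aggregate_features <- function(cycles, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  if (length(cycles) == 0L) stop("no cycles to aggregate")
  per <- vapply(cycles, cyclogram_features,
                numeric(length(CYCLOGRAM_FEATURES)))
  fun <- if (combine == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  fun(per)
}
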