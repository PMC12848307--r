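# Vessel- and cell-level geometric measurements: diameter from wall-peak
# intensity profiles, polyline vessel length, cell width/length from area and
# aspect ratio, and effective cell numbers along the two vessel axes.

#' Measure vessel diameter from a wall-peak intensity profile
#'
#' A line drawn perpendicular to a fluorescently labelled vessel yields an
#' intensity profile with two peaks at the vessel walls. The baseline is
#' estimated as the median of the outer 10 percent of samples on each side;
#' the two most prominent local maxima are taken as the walls. For each wall
#' the two half-maximum crossings (linear interpolation; half-maximum =
#' baseline + 0.5 * (peak - baseline)) define the wall centre as their
#' midpoint, and the diameter is the centre-to-centre distance. This
#' convention is unbiased by membrane-label thickness and symmetric under
#' left-right mirroring of the profile.
#'
#' @param profile an [IntensityProfile-class] with at least 8 samples and
#'   baseline-dominated ends.
#' @param minProminence minimum peak prominence as a fraction of
#'   (max - baseline); default 0.2.
#' @return A [DiameterEstimate-class].
#' @examples
#' g <- genWallProfile(wallCenters = c(2, 12))
#' diameter(diameterFromProfile(g$profile))
#' @export
diameterFromProfile <- function(profile, minProminence = 0.2) {
  stopifnot(is(profile, "IntensityProfile"))
  x <- profile@positions; y <- profile@intensities
  n <- length(x)
  if (n < 8) stop("walls not found: profile has fewer than 8 samples")
  nEdge <- max(2L, floor(0.1 * n))
  baseline <- median(c(y[seq_len(nEdge)], y[seq(n - nEdge + 1, n)]))
  amp <- max(y) - baseline
  if (amp <= 0) stop("walls not found: no signal above baseline")
  pk <- pracma::findpeaks(y, minpeakheight = baseline + minProminence * amp)
  if (!is.null(pk)) {
    # prominence relative to the higher flanking trough reported by findpeaks
    prom <- pk[, 1] - pmax(y[pk[, 3]], y[pk[, 4]])
    pk <- pk[prom >= minProminence * amp, , drop = FALSE]
    prom <- prom[prom >= minProminence * amp]
  }
  if (is.null(pk) || nrow(pk) < 2)
    stop("walls not found: fewer than two sufficiently prominent peaks")
  pk <- pk[order(prom, decreasing = TRUE)[1:2], , drop = FALSE]
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  walls <- lapply(seq_len(2), function(k)
    .wallHalfMax(x, y, peakIdx = pk[k, 2], baseline = baseline))
  if (walls[[1]]$right >= walls[[2]]$left)
    stop("walls unresolvable: half-maximum intervals overlap")
  centres <- c(walls[[1]]$centre, walls[[2]]$centre)
  new("DiameterEstimate", diameter = diff(centres), wallPositions = centres,
      nProfilesAveraged = 1L)
}

# Half-max crossings flanking a peak, by linear interpolation on the sampled
# profile; returns the crossing pair and their midpoint (the wall centre).
.wallHalfMax <- function(x, y, peakIdx, baseline) {
  half <- baseline + 0.5 * (y[peakIdx] - baseline)
  left <- NA_real_
  for (i in seq(peakIdx, 2)) {
    if (y[i - 1] <= half && y[i] > half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) *
        (x[i] - x[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(peakIdx, length(x) - 1)) {
    if (y[i] > half && y[i + 1] <= half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("walls not found: half-maximum crossing missing for a peak")
  list(left = left, right = right, centre = (left + right) / 2)
}

#' Average repeated diameter measurements of one vessel
#'
#' Repeated line profiles of the same vessel are averaged arithmetically;
#' at least three measurements per vessel are expected, and fewer trigger a
#' warning (configurable).
#'
#' @param estimates a list of [DiameterEstimate-class] objects (or a numeric
#'   vector of diameters).
#' @param minN minimum number of measurements before warning; default 3.
#' @param warnInsufficient warn (default) or error when fewer than `minN`.
#' @return A [DiameterEstimate-class] with `nProfilesAveraged` set.
#' @export
meanDiameter <- function(estimates, minN = 3L, warnInsufficient = TRUE) {
  d <- if (is.numeric(estimates)) estimates
       else vapply(estimates, diameter, numeric(1))
  if (length(d) < minN) {
    msg <- sprintf("insufficient measurements: %d < %d", length(d), minN)
    if (warnInsufficient) warning(msg) else stop(msg)
  }
  new("DiameterEstimate", diameter = mean(d),
      wallPositions = c(NA_real_, NA_real_),
      nProfilesAveraged = length(d))
}

#' Length of a traced polyline
#'
#' The vessel spine is traced manually as an ordered polyline; its length is
#' the sum of Euclidean segment lengths. Works for 2D or 3D points.
#'
#' @param points numeric matrix, one point per row (>= 2 rows).
#' @return Length in the units of `points` (µm).
#' @examples
#' polylineLength(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polylineLength <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("degenerate polyline: fewer than 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Cell width and length from area and aspect ratio
#'
#' An unwrapped endothelial cell with area `a` and aspect ratio `r`
#' (axial / radial) has radial width w = sqrt(a / r) and axial length
#' l = sqrt(r * a), so that w * l = a and l / w = r exactly.
#'
#' @param a cell area (µm²), > 0; vectorised.
#' @param r aspect ratio (dimensionless), > 0.
#' @return A list with numeric vectors `w` and `l` (µm).
#' @examples
#' cellWidthLength(100, 4)  # w = 5, l = 20
#' @export
cellWidthLength <- function(a, r) {
  if (any(!is.finite(a)) || any(!is.finite(r)) || any(a <= 0) || any(r <= 0))
    stop("invalid shape: area and aspect ratio must be positive")
  list(w = sqrt(a / r), l = sqrt(r * a))
}

#' Effective cell numbers along the vessel axes
#'
#' The number of cells spanning the vessel circumference is
#' N_eff(radial) = pi * D / w, and along the axis N_eff(axial) = L / l,
#' where D is vessel diameter, L vessel length, and w, l the cell width and
#' length.
#'
#' @param D vessel diameter (µm).
#' @param L vessel length (µm).
#' @param w cell width (µm).
#' @param l cell length (µm).
#' @return A list with `radial` and `axial` effective cell numbers.
#' @examples
#' effectiveCellNumbers(D = 10, L = 100, w = 5, l = 20)
#' @export
effectiveCellNumbers <- function(D, L, w, l) {
  stopIfNotPositive(D, L, w, l, msg = "invalid geometry: inputs must be > 0")
  list(radial = pi * D / w, axial = L / l)
}

#' Extract an intensity profile from an image along a line
#'
#' Samples an image by bilinear interpolation along a straight line given by
#' a start pixel, an angle and a length, producing an
#' [IntensityProfile-class] ready for [diameterFromProfile()].
#'
#' @param image numeric matrix (row 1 = top).
#' @param row,col start position (pixels, 1-based).
#' @param angle direction in degrees (0 = along increasing column).
#' @param length line length in µm.
#' @param pixelSize µm per pixel.
#' @return An [IntensityProfile-class].
#' @export
profileFromImage <- function(image, row, col, angle, length,
                             pixelSize = 0.1) {
  stopIfNotPositive(pixelSize, length, msg = "length and pixelSize must be > 0")
  nSamp <- max(2L, ceiling(length / pixelSize) + 1L)
  s <- seq(0, length, length.out = nSamp)
  th <- angle * pi / 180
  rr <- row + s / pixelSize * sin(th)
  cc <- col + s / pixelSize * cos(th)
  if (any(rr < 1 | rr > nrow(image) | cc < 1 | cc > ncol(image)))
    stop("profile line leaves the image")
  r0 <- floor(rr); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, nrow(image)); c1 <- pmin(c0 + 1, ncol(image))
  fr <- rr - r0; fc <- cc - c0
  v <- image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c1)] * (1 - fr) * fc +
    image[cbind(r1, c1)] * fr * fc
  intensityProfile(s, v, pixelSize)
}
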