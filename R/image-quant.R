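# Intensity-trace and kymograph quantifications: background subtraction and
# log/max-min normalisation, junction-to-cortex intensity ratios, ablation
# recoil velocimetry, cross-correlation lag estimation, and the heuristic
# structure-tensor classifier of cortical actin organisation.

#' Subtract a background level from an intensity trace
#'
#' @param trace an [IntensityTrace-class].
#' @param backgroundMean mean intensity of a background region (a.u.).
#' @return The shifted [IntensityTrace-class].
#' @export
backgroundSubtract <- function(trace, backgroundMean) {
  stopifnot(is(trace, "IntensityTrace"), is.finite(backgroundMean))
  intensityTrace(trace@times, trace@values - backgroundMean, trace@channel)
}

#' Log10 and max-min normalise an intensity trace
#'
#' Values are clipped from below at `floorFraction` times the series maximum
#' (with a warning when clipping occurs, e.g. after background subtraction),
#' converted to log10, and rescaled so the minimum maps to 0 and the maximum
#' to 1. Puts channels with different gains on a common scale.
#'
#' @param trace an [IntensityTrace-class] with >= 2 samples.
#' @param floorFraction clipping floor as a fraction of the series maximum;
#'   default 1e-4.
#' @return The normalised [IntensityTrace-class] with values in [0, 1].
#' @examples
#' tr <- intensityTrace(1:3, c(1, 10, 100))
#' traceValues(logMinmaxNormalize(tr))  # 0, 0.5, 1
#' @export
logMinmaxNormalize <- function(trace, floorFraction = 1e-4) {
  stopifnot(is(trace, "IntensityTrace"))
  v <- trace@values
  if (length(v) < 2) stop("need at least 2 samples")
  top <- max(v)
  if (top <= 0) stop("zero dynamic range: no positive values")
  floorVal <- floorFraction * top
  if (any(v < floorVal)) {
    warning("values at or below the clipping floor were clipped before log10")
    v <- pmax(v, floorVal)
  }
  lv <- log10(v)
  rng <- range(lv)
  if (diff(rng) == 0) stop("zero dynamic range: constant series")
  intensityTrace(trace@times, (lv - rng[1]) / diff(rng), trace@channel)
}

#' Junction-to-cortex intensity ratio
#'
#' Mean ROI intensities along cell-cell junctions and over cortical actin are
#' background-subtracted (background = mean of the background-region means)
#' and their ratio is reported on a log10 scale, one value per vessel.
#' Positive values indicate junctional enrichment. The canonical ROI counts
#' (6 junction, 10 cortex, 2 background) are defaults, not hard limits.
#'
#' @param junctionMeans numeric, per-ROI junctional means (a.u.).
#' @param cortexMeans numeric, per-ROI cortical means (a.u.).
#' @param backgroundMeans numeric, background-region means (a.u.).
#' @param expectedCounts integer length 3 used for a consistency warning;
#'   default c(6, 10, 2). Set to `NULL` to skip the check.
#' @return A list: `log10Ratio`, background-subtracted `junctionMean` and
#'   `cortexMean`, and `background`.
#' @examples
#' junctionCortexRatio(rep(21, 6), rep(3, 10), c(1, 1))$log10Ratio  # 1
#' @export
junctionCortexRatio <- function(junctionMeans, cortexMeans, backgroundMeans,
                                expectedCounts = c(6L, 10L, 2L)) {
  if (!is.null(expectedCounts)) {
    got <- c(length(junctionMeans), length(cortexMeans),
             length(backgroundMeans))
    if (any(got != expectedCounts))
      warning(sprintf("ROI counts %s differ from the canonical %s",
                      paste(got, collapse = "/"),
                      paste(expectedCounts, collapse = "/")))
  }
  bg <- mean(backgroundMeans)
  jm <- mean(junctionMeans) - bg
  cm <- mean(cortexMeans) - bg
  if (jm <= 0 || cm <= 0)
    stop("signal below background: background-subtracted mean is not positive")
  list(log10Ratio = log10(jm / cm), junctionMean = jm, cortexMean = cm,
       background = bg)
}

#' Trace the ablation gap on a kymograph
#'
#' For each post-ablation time column, the gap between the retracting cortex
#' edges is measured as the distance between the two inner crossings of a
#' fractional threshold flanking the intensity minimum: on each side the
#' threshold level is min + `thresholdFraction` * (flank maximum - min), and
#' the crossing is located with sub-pixel linear interpolation. Columns
#' without sufficient contrast (less than `minContrast` of the kymograph's
#' dynamic range) and pre-ablation columns are returned as `NA`, never as
#' zero. The measurement is invariant under affine intensity rescaling of
#' the kymograph.
#'
#' @param kymo a [Kymograph-class].
#' @param thresholdFraction fractional threshold between the local minimum
#'   and the flanking maxima; default 0.5.
#' @param minContrast minimum column contrast as a fraction of the
#'   kymograph's global dynamic range; default 0.25.
#' @return Numeric vector of gap widths (µm), one per frame; `NA` where no
#'   gap is detectable.
#' @export
traceGapEdges <- function(kymo, thresholdFraction = 0.5, minContrast = 0.25) {
  stopifnot(is(kymo, "Kymograph"))
  m <- kymo@matrix
  globalRange <- diff(range(m))
  if (globalRange <= 0) stop("flat kymograph: no gap present")
  x <- (seq_len(nrow(m)) - 0.5) * kymo@pixelSize
  out <- rep(NA_real_, ncol(m))
  for (k in seq(kymo@ablationFrame, ncol(m))) {
    col <- m[, k]
    iMin <- which.min(col)
    leftMax <- if (iMin > 1) max(col[1:iMin]) else -Inf
    rightMax <- if (iMin < length(col)) max(col[iMin:length(col)]) else -Inf
    contrast <- min(leftMax, rightMax) - col[iMin]
    if (!is.finite(contrast) || contrast < minContrast * globalRange) next
    lev <- function(flank) col[iMin] + thresholdFraction * (flank - col[iMin])
    # inner crossing on the left of the minimum
    lv <- lev(leftMax); xl <- NA_real_
    for (i in seq(iMin, 2)) {
      if (col[i] <= lv && col[i - 1] > lv) {
        xl <- x[i - 1] + (col[i - 1] - lv) / (col[i - 1] - col[i]) *
          (x[i] - x[i - 1])
        break
      }
    }
    rv <- lev(rightMax); xr <- NA_real_
    for (i in seq(iMin, length(col) - 1)) {
      if (col[i] <= rv && col[i + 1] > rv) {
        xr <- x[i] + (rv - col[i]) / (col[i + 1] - col[i]) * (x[i + 1] - x[i])
        break
      }
    }
    if (!is.na(xl) && !is.na(xr)) out[k] <- xr - xl
  }
  out
}

#' Recoil velocity from a gap-distance series
#'
#' The mean recoil velocity over the first `window` seconds after ablation:
#' the change in gap distance between the ablation frame and the end of the
#' window, divided by the elapsed time (for uniform sampling this equals the
#' mean of the per-frame velocities). A least-squares slope over the same
#' window is returned alongside as a cross-check.
#'
#' @param gap numeric gap widths (µm), `NA` before ablation / where missing.
#' @param times frame times (s), same length as `gap`.
#' @param window averaging window after ablation (s); default 10.
#' @return A list: `velocity` (µm/s), `slope` (least-squares, µm/s),
#'   `window` (s actually spanned), `nFrames` used.
#' @export
recoilVelocity <- function(gap, times, window = 10) {
  stopifnot(length(gap) == length(times), window > 0)
  ok <- which(!is.na(gap))
  if (length(ok) < 2) stop("window too short: fewer than 2 valid frames")
  t0 <- times[ok[1]]
  inWin <- ok[times[ok] <= t0 + window + 1e-9]
  if (length(inWin) < 2) stop("window too short: fewer than 2 frames in window")
  first <- inWin[1]; last <- inWin[length(inWin)]
  elapsed <- times[last] - times[first]
  fit <- stats::lm(gap[inWin] ~ times[inWin])
  list(velocity = (gap[last] - gap[first]) / elapsed,
       slope = unname(coef(fit)[2]), window = elapsed,
       nFrames = length(inWin))
}

#' Combine per-ROI recoil velocities into a vessel-level result
#'
#' Three line ROIs are drawn across each ablation gap; their mean velocities
#' are averaged into the final per-vessel recoil velocity.
#'
#' @param perRoiVelocity numeric, per-ROI mean velocities (µm/s);
#'   canonically 3 values.
#' @param window averaging window used (s).
#' @return A list: `perRoiVelocity`, `meanVelocity`, `window`.
#' @export
meanRecoil <- function(perRoiVelocity, window = 10) {
  if (length(perRoiVelocity) != 3)
    warning("canonically three line ROIs are averaged per ablation")
  list(perRoiVelocity = perRoiVelocity,
       meanVelocity = mean(perRoiVelocity), window = window)
}

#' Cross-correlation lag between two traces
#'
#' Normalised cross-correlation over integer frame lags up to `maxLag`, with
#' parabolic sub-sample refinement around the chosen extremum. A positive
#' lag means the first trace leads the second. By default the extremum of
#' largest magnitude is reported; `which` selects the most negative or most
#' positive correlation instead (used for width-alignment analysis, where
#' the anticipated coupling is negative).
#'
#' @param a,b [IntensityTrace-class] objects on the same uniform time grid
#'   (or plain numeric vectors with `dt` supplied).
#' @param maxLag maximum |lag| scanned, in time units; must be below half
#'   the record length.
#' @param which "extremum" (largest |r|), "min" or "max".
#' @param dt sampling interval, required when `a`, `b` are plain vectors.
#' @param refine logical, parabolic sub-sample refinement (default TRUE).
#' @return A list: `lag` (time units; positive = `a` leads), `correlation`
#'   (signed, at the integer-lag extremum), `lags`, `r` (the full scan).
#' @examples
#' g <- genLaggedSeries(trueLag = 2.5, noiseSd = 0, seed = 1)
#' crosscorrLag(g$a, g$b, maxLag = 10)$lag
#' @export
crosscorrLag <- function(a, b, maxLag, which = c("extremum", "min", "max"),
                         dt = NULL, refine = TRUE) {
  which <- match.arg(which)
  if (is(a, "IntensityTrace")) {
    stopifnot(is(b, "IntensityTrace"),
              length(a@times) == length(b@times))
    dt <- median(diff(a@times))
    a <- a@values; b <- b@values
  }
  if (is.null(dt) || dt <= 0) stop("dt must be supplied for plain vectors")
  n <- length(a)
  K <- floor(maxLag / dt + 1e-9)
  if (K >= n / 2) stop("insufficient samples: maxLag >= half the record")
  if (n - K < 3) stop("insufficient samples")
  lags <- -K:K
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      ia <- 1:(n - k); ib <- (1 + k):n       # b delayed: b[t+k] vs a[t]
    } else {
      ia <- (1 - k):n; ib <- 1:(n + k)
    }
    av <- a[ia]; bv <- b[ib]
    if (sd(av) == 0 || sd(bv) == 0) return(0)
    cor(av, bv)
  }, numeric(1))
  i <- switch(which, extremum = which.max(abs(r)), min = which.min(r),
              max = which.max(r))
  lag <- lags[i] * dt
  if (refine && i > 1 && i < length(lags)) {
    # parabolic vertex through the three points around the extremum, on a
    # sign-adjusted scale so minima and maxima are treated alike
    s <- if (r[i] < 0) -1 else 1
    y1 <- s * r[i - 1]; y2 <- s * r[i]; y3 <- s * r[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps)
      lag <- lag + 0.5 * (y1 - y3) / den * dt
  }
  list(lag = lag, correlation = r[i], lags = lags * dt, r = r)
}

#' Classify cortical actin organisation from an image texture
#'
#' Structure-tensor heuristic approximating the manual circumferential (C) /
#' mesh (M) / longitudinal (L) annotation: image gradients are pooled into
#' the energy-weighted 2x2 structure tensor, whose dominant eigenvector
#' gives the texture orientation and whose eigenvalue anisotropy gives a
#' coherence in [0, 1]. Low coherence is called M; otherwise the dominant
#' angle within `angleBand` of the vessel long axis is called L, within
#' `angleBand` of the perpendicular C, and anything in between M. Angle
#' convention: 0 degrees = vessel long (axial) axis. This classifier is an
#' explicitly approximate, global baseline: it does not resolve mixed
#' classes the way an annotator can.
#'
#' @param image numeric matrix; the vessel axis direction is given by
#'   `vesselAxisAngle` (degrees, 0 = along columns/x).
#' @param vesselAxisAngle orientation of the vessel long axis in the image
#'   (degrees); default 0.
#' @param coherenceThreshold below this the texture is isotropic -> "M";
#'   default 0.2.
#' @param angleBand half-width of the angular acceptance band (degrees);
#'   default 30.
#' @return An [OrientationCall-class].
#' @examples
#' tex <- genOrientedTexture("L")
#' orientationLabel(classifyOrientation(tex$image))
#' @export
classifyOrientation <- function(image, vesselAxisAngle = 0,
                                coherenceThreshold = 0.2, angleBand = 30) {
  image <- as.matrix(image)
  if (length(image) < 9 || diff(range(image)) == 0)
    stop("no texture: image is empty or flat")
  # central-difference gradients; x = columns, y = rows
  gx <- (image[, c(2:ncol(image), ncol(image))] -
           image[, c(1, 1:(ncol(image) - 1))]) / 2
  gy <- (image[c(2:nrow(image), nrow(image)), ] -
           image[c(1, 1:(nrow(image) - 1)), ]) / 2
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  tr <- jxx + jyy
  if (tr <= 0) stop("no texture: zero gradient energy")
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr
  # dominant gradient direction; the texture (stripe) direction is 90 deg off
  gradAngle <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  texAngle <- gradAngle + 90
  # angle relative to the vessel long axis, folded into [0, 90]
  rel <- abs(((texAngle - vesselAxisAngle) + 90) %% 180 - 90)
  label <- if (coh < coherenceThreshold) "M"
           else if (rel <= angleBand) "L"
           else if (rel >= 90 - angleBand) "C"
           else "M"
  new("OrientationCall", label = label, dominantAngle = rel, coherence = coh)
}

#' Combine front and back orientation calls into a vessel-level label
#'
#' The two dorsal views of a vessel are classified independently; equal
#' labels collapse to the single class, unequal labels produce the ordered
#' combined category (C before M before L): C-M, M-L or C-L.
#'
#' @param front,back [OrientationCall-class] objects (or bare labels).
#' @return Character, one of "C", "M", "L", "C-M", "M-L", "C-L".
#' @examples
#' combineViews("M", "C")  # "C-M"
#' @export
combineViews <- function(front, back) {
  lab <- function(x) if (is(x, "OrientationCall")) x@label else
    match.arg(x, c("C", "M", "L"))
  f <- lab(front); b <- lab(back)
  if (f == b) return(f)
  ord <- c(C = 1L, M = 2L, L = 3L)
  labs <- c(f, b)
  paste(labs[order(ord[labs])], collapse = "-")
}
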