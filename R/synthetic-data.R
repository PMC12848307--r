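# Seeded synthetic-data generators. Every generator returns its data together
# with machine-readable ground truth, so every downstream operation can be
# tested by parameter recovery without any microscopy data. All generators are
# deterministic given (spec, seed); noiseless outputs match their closed-form
# definitions to floating-point tolerance.

#' Generate a synthetic vessel-wall intensity profile
#'
#' Emulates the 1D intensity profile obtained by drawing a line perpendicular
#' to a fluorescently labelled vessel: two wall peaks (triangular or
#' Gaussian) on a flat baseline plus optional i.i.d. Gaussian noise. The true
#' diameter under the wall-centre convention of [diameterFromProfile()] is
#' the distance between the two wall centres.
#'
#' @param wallCenters numeric length 2, wall-centre positions (µm), distinct.
#' @param wallShape "triangle" or "gaussian".
#' @param wallHalfwidth half-width of a triangular wall, or the Gaussian
#'   sigma (µm); must be > 0.
#' @param wallHeight peak intensity above baseline (a.u.).
#' @param baseline baseline intensity (a.u.).
#' @param noiseSd standard deviation of additive Gaussian noise (a.u.).
#' @param pixelSize sampling interval (µm/px); default 0.1 µm matches a
#'   high-NA 60x acquisition regime.
#' @param margin extra baseline on each side of the walls (µm).
#' @param seed integer seed for the noise stream, or `NULL`.
#' @return A list with `profile` (an [IntensityProfile-class]), `noiseless`
#'   (the analytic profile on the same grid) and `trueDiameter` (µm).
#' @examples
#' g <- genWallProfile(wallCenters = c(2, 12))
#' g$trueDiameter
#' @export
genWallProfile <- function(wallCenters = c(2, 12),
                           wallShape = c("triangle", "gaussian"),
                           wallHalfwidth = 0.5, wallHeight = 1,
                           baseline = 0.1, noiseSd = 0, pixelSize = 0.1,
                           margin = 3, seed = NULL) {
  wallShape <- match.arg(wallShape)
  stopIfNotPositive(wallHalfwidth, pixelSize,
                    msg = "wallHalfwidth and pixelSize must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  wallCenters <- sort(as.numeric(wallCenters))
  if (length(wallCenters) != 2 || diff(wallCenters) == 0)
    stop("wallCenters must be two distinct positions")
  if (diff(wallCenters) < 2 * wallHalfwidth)
    stop("walls unresolvable: separation below twice the wall halfwidth")
  x <- seq(wallCenters[1] - margin, wallCenters[2] + margin, by = pixelSize)
  wall <- function(c0) {
    if (wallShape == "triangle")
      wallHeight * pmax(0, 1 - abs(x - c0) / wallHalfwidth)
    else wallHeight * exp(-(x - c0)^2 / (2 * wallHalfwidth^2))
  }
  clean <- baseline + wall(wallCenters[1]) + wall(wallCenters[2])
  noisy <- if (noiseSd > 0)
    withLocalSeed(seed, clean + rnorm(length(x), 0, noiseSd)) else clean
  list(profile = intensityProfile(x, noisy, pixelSize),
       noiseless = intensityProfile(x, clean, pixelSize),
       trueDiameter = diff(wallCenters))
}

#' Generate synthetic per-cell shape and per-vessel geometry tables
#'
#' Emulates the measurement tables of a longitudinal vessel-remodelling
#' study: per-timepoint cell area and aspect ratio for `nCells` unwrapped
#' endothelial cells, and per-vessel diameter and length for `nVessels`
#' vessels. Multiplicative lognormal noise with coefficient of variation
#' `noiseCv` is applied (mean-corrected, so expectations equal the
#' prescribed true values). Ground-truth interval strains are computed in
#' closed form from the prescribed values and attached.
#'
#' @param nCells cells per timepoint.
#' @param timepoints character vector of timepoint labels.
#' @param trueArea,trueAspect per-timepoint true cell area (µm²) and aspect
#'   ratio (axial/radial, dimensionless); recycled to `length(timepoints)`.
#' @param trueDiameter,trueLength per-timepoint true vessel diameter and
#'   length (µm).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nVessels vessels per timepoint.
#' @param seed integer seed, or `NULL`.
#' @return A list with `cells` and `vessels` data.frames (headers as written
#'   by [writeCellTable()] / [writeVesselTable()]) and `truth`, itself a list
#'   with the prescribed means and the closed-form [IntervalStrains-class]
#'   per consecutive interval plus the sampling standard errors of the group
#'   means.
#' @examples
#' g <- genCellShapeTable(nCells = 5, noiseCv = 0, seed = 1)
#' head(g$cells)
#' @export
genCellShapeTable <- function(nCells = 20,
                              timepoints = c("2dpf", "3dpf", "4dpf"),
                              trueArea = c(420, 340, 260),
                              trueAspect = c(3, 3, 3),
                              trueDiameter = c(8.5, 7.5, 6.5),
                              trueLength = c(60, 70, 80),
                              noiseCv = 0.1, nVessels = 8, seed = NULL) {
  nt <- length(timepoints)
  trueArea <- rep_len(trueArea, nt); trueAspect <- rep_len(trueAspect, nt)
  trueDiameter <- rep_len(trueDiameter, nt)
  trueLength <- rep_len(trueLength, nt)
  stopIfNotPositive(trueArea, trueAspect, trueDiameter, trueLength,
                    msg = "all true values must be > 0")
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  # mean-corrected lognormal: E[X] = mu, sd[X]/E[X] = noiseCv (to first order)
  sdlog <- sqrt(log(1 + noiseCv^2))
  rmult <- function(n, mu)
    if (noiseCv == 0) rep(mu, n) else rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
  withLocalSeed(seed, {
    cells <- do.call(rbind, lapply(seq_len(nt), function(k) {
      a <- rmult(nCells, trueArea[k])
      r <- rmult(nCells, trueAspect[k])
      wl <- cellWidthLength(a, r)
      data.frame(cell_id = sprintf("c%02d", seq_len(nCells)),
                 vessel_id = sprintf("v%02d", ((seq_len(nCells) - 1) %%
                                                 nVessels) + 1),
                 timepoint = timepoints[k], area_um2 = a, aspect_ratio = r,
                 width_um = wl$w, length_um = wl$l)
    }))
    vessels <- do.call(rbind, lapply(seq_len(nt), function(k) {
      data.frame(vessel_id = sprintf("v%02d", seq_len(nVessels)),
                 timepoint = timepoints[k],
                 diameter_um = rmult(nVessels, trueDiameter[k]),
                 length_um = rmult(nVessels, trueLength[k]),
                 ec_count = NA_integer_)
    }))
    truth <- .closedFormTruth(timepoints, trueArea, trueAspect, trueDiameter,
                              trueLength, noiseCv, nCells, nVessels)
    list(cells = cells, vessels = vessels, truth = truth)
  })
}

# Closed-form ground truth: true w, l, effective cell numbers and the six
# strains per consecutive interval, all by direct arithmetic on the
# prescribed values (independent of the estimation path).
.closedFormTruth <- function(tp, area, aspect, D, L, cv, nCells, nVessels) {
  w <- sqrt(area / aspect); l <- sqrt(aspect * area)
  nr <- pi * D / w; na <- L / l
  strains <- list()
  for (k in seq_len(length(tp) - 1)) {
    strains[[paste(tp[k], tp[k + 1], sep = "->")]] <- new("IntervalStrains",
      interval = c(tp[k], tp[k + 1]),
      epsVesselRadial = (D[k + 1] - D[k]) / D[k],
      epsVesselAxial = (L[k + 1] - L[k]) / L[k],
      epsCellRadial = (w[k + 1] - w[k]) / w[k],
      epsCellAxial = (l[k + 1] - l[k]) / l[k],
      epsNumberRadial = (pi * D[k + 1] / w[k + 1]) / (pi * D[k] / w[k]) - 1,
      epsNumberAxial = (L[k + 1] / l[k + 1]) / (L[k] / l[k]) - 1)
  }
  list(timepoints = tp, area = area, aspect = aspect, diameter = D,
       length = L, width = w, cellLength = l, neffRadial = nr, neffAxial = na,
       strains = strains,
       seMeanArea = area * cv / sqrt(nCells),
       seMeanDiameter = D * cv / sqrt(nVessels))
}

#' Generate a synthetic post-ablation kymograph
#'
#' Emulates the kymograph of a laser-ablation experiment: uniform cortical
#' signal before the ablation frame, then a dark gap whose width grows
#' linearly at `trueVelocity`. Edges are smoothed with a Gaussian of width
#' `edgeBlur` (analytically, via the normal CDF) and i.i.d. Gaussian noise is
#' added.
#'
#' @param trueVelocity gap-opening velocity (µm/s), >= 0.
#' @param frameInterval s per frame.
#' @param nFrames number of frames.
#' @param pixelSize µm per row.
#' @param initialGap gap width at the ablation frame (µm).
#' @param edgeBlur Gaussian edge smoothing (µm).
#' @param noiseSd additive noise sd (a.u.; signal amplitude is 1).
#' @param fieldWidth spatial extent of the line ROI (µm).
#' @param ablationFrame frame index of the ablation.
#' @param seed integer seed, or `NULL`.
#' @return A list with `kymograph` (a [Kymograph-class]), `noiseless`
#'   (matrix) and `trueGap`, the per-frame true gap width (µm; `NA` before
#'   ablation).
#' @export
genKymograph <- function(trueVelocity = 0.4, frameInterval = 0.25,
                         nFrames = 50, pixelSize = 0.1, initialGap = 1,
                         edgeBlur = 0.1, noiseSd = 0, fieldWidth = 12,
                         ablationFrame = 5L, seed = NULL) {
  stopIfNotPositive(frameInterval, pixelSize, fieldWidth, initialGap,
                    msg = "frameInterval, pixelSize, fieldWidth, initialGap must be > 0")
  if (trueVelocity < 0) stop("trueVelocity must be >= 0")
  x <- seq(pixelSize / 2, fieldWidth - pixelSize / 2, by = pixelSize)
  centre <- fieldWidth / 2
  tsince <- (seq_len(nFrames) - ablationFrame) * frameInterval
  gap <- ifelse(tsince < 0, NA_real_, initialGap + trueVelocity * tsince)
  if (max(gap, na.rm = TRUE) >= fieldWidth - 4 * max(edgeBlur, pixelSize))
    stop("gap out of field: widen fieldWidth or shorten the movie")
  clean <- vapply(seq_len(nFrames), function(k) {
    if (is.na(gap[k])) return(rep(1, length(x)))
    eL <- centre - gap[k] / 2; eR <- centre + gap[k] / 2
    if (edgeBlur > 0)
      1 - (stats::pnorm((x - eL) / edgeBlur) -
             stats::pnorm((x - eR) / edgeBlur))
    else 1 - as.numeric(x > eL & x < eR)
  }, numeric(length(x)))
  noisy <- if (noiseSd > 0)
    withLocalSeed(seed, clean + rnorm(length(clean), 0, noiseSd)) else clean
  list(kymograph = kymograph(noisy, pixelSize, frameInterval, ablationFrame),
       noiseless = clean, trueGap = gap)
}

#' Generate a pair of time series with a known lead-lag relation
#'
#' Emulates paired width / alignment readouts: a smooth autocorrelated base
#' series A (Gaussian noise low-pass filtered with a moving average), and
#' B(t) = s * A(t - lag) + noise with s = +1 or -1. Used to validate
#' [crosscorrLag()] and [widthAlignmentLag()].
#'
#' @param nFrames length of the series.
#' @param frameInterval time per frame (any unit; the lag is returned in the
#'   same unit).
#' @param trueLag signed lag by which B trails A; rounded to an integer
#'   number of frames (the realised value is returned in `truth`).
#' @param correlationSign "positive" or "negative".
#' @param noiseSd sd of additive noise on B, relative to sd(A) = 1.
#' @param smoothFrames width of the moving-average smoother defining the
#'   autocorrelation time of A.
#' @param seed integer seed, or `NULL`.
#' @return A list with `a`, `b` ([IntensityTrace-class]) and `truth`
#'   (realised lag in time units and in frames, and the sign).
#' @export
genLaggedSeries <- function(nFrames = 200, frameInterval = 0.5, trueLag = 2.5,
                            correlationSign = c("negative", "positive"),
                            noiseSd = 0.1, smoothFrames = 9, seed = NULL) {
  correlationSign <- match.arg(correlationSign)
  stopIfNotPositive(frameInterval, msg = "frameInterval must be > 0")
  lagFrames <- round(trueLag / frameInterval)
  if (abs(lagFrames) >= nFrames / 2)
    stop("|trueLag| must be below half the record length")
  s <- if (correlationSign == "negative") -1 else 1
  withLocalSeed(seed, {
    pad <- abs(lagFrames) + smoothFrames
    base <- rollMean(rnorm(nFrames + 2 * pad), smoothFrames)
    base <- (base - mean(base)) / sd(base)
    idxA <- pad + seq_len(nFrames)
    a <- base[idxA]
    b <- s * base[idxA - lagFrames] +
      if (noiseSd > 0) rnorm(nFrames, 0, noiseSd) else 0
    tt <- (seq_len(nFrames) - 1) * frameInterval
    list(a = intensityTrace(tt, a, "A"), b = intensityTrace(tt, b, "B"),
         truth = list(lag = lagFrames * frameInterval, lagFrames = lagFrames,
                      sign = s))
  })
}

#' Generate a synthetic oriented cortical actin texture
#'
#' Emulates the three cortical actin organisations seen on unwrapped vessel
#' walls. The vessel long (axial) axis runs along image columns (x);
#' "L" (longitudinal) textures are stripes along that axis, "C"
#' (circumferential) stripes run perpendicular to it, and "M" (mesh) is an
#' isotropic superposition of cross-hatched stripes. A global orientation
#' jitter (degrees) and additive noise can be applied.
#'
#' @param label "C", "M" or "L".
#' @param imageSize integer length 2, rows x columns.
#' @param stripePeriod stripe period in px (>= 2).
#' @param angleJitterSd sd of the global orientation jitter (degrees).
#' @param noiseSd additive Gaussian noise sd (stripe amplitude is 1).
#' @param seed integer seed, or `NULL`.
#' @return A list with `image` (numeric matrix) and `truth` (label and the
#'   realised jitter angle).
#' @export
genOrientedTexture <- function(label = c("C", "M", "L"),
                               imageSize = c(96, 96), stripePeriod = 8,
                               angleJitterSd = 0, noiseSd = 0, seed = NULL) {
  label <- match.arg(label)
  if (stripePeriod < 2) stop("stripePeriod must be >= 2 px")
  withLocalSeed(seed, {
    jit <- if (angleJitterSd > 0) rnorm(1, 0, angleJitterSd) else 0
    nr <- imageSize[1]; nc <- imageSize[2]
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    stripes <- function(angleDeg) {
      # stripes whose crests run along direction angleDeg (0 = x/axial axis)
      th <- (angleDeg) * pi / 180
      phase <- (-sin(th) * col + cos(th) * row) * 2 * pi / stripePeriod
      sin(phase)
    }
    img <- switch(label,
      L = stripes(0 + jit),
      C = stripes(90 + jit),
      M = (stripes(45 + jit) + stripes(-45 + jit)) / sqrt(2))
    if (noiseSd > 0) img <- img + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
    list(image = img, truth = list(label = label, jitterDeg = jit))
  })
}

## ---------------------------------------------------------------------------
## External interfaces: TIFF / CSV / JSON sidecars
## ---------------------------------------------------------------------------

#' Write and read pipeline artifacts
#'
#' Images are written as (multi-frame) TIFF, measurement tables as headed
#' CSV, and ground truth as JSON sidecars. `writeImageTiff()` rescales to
#' [0, 1] as required by the TIFF writer and stores the original range in a
#' JSON sidecar when `truth` is supplied.
#'
#' @param image numeric matrix (or [Kymograph-class] for `writeKymographTiff`).
#' @param path output file path.
#' @param truth optional list written as `<path>.json`.
#' @return `path`, invisibly.
#' @name io
#' @export
writeImageTiff <- function(image, path, truth = NULL) {
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  if (!is.null(truth))
    jsonlite::write_json(c(truth, list(intensityRange = rng)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @param kymo a [Kymograph-class].
#' @export
writeKymographTiff <- function(kymo, path, truth = NULL) {
  meta <- list(pixelSize = kymo@pixelSize, frameInterval = kymo@frameInterval,
               ablationFrame = kymo@ablationFrame)
  writeImageTiff(kymo@matrix, path, truth = c(meta, truth))
}

#' @rdname io
#' @param cells,vessels data.frames as produced by [genCellShapeTable()].
#' @export
writeCellTable <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
writeVesselTable <- function(vessels, path) {
  utils::write.csv(vessels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @examples
#' cells <- readCellTable(system.file("extdata", "example_cells.csv",
#'                                    package = "vesselmech"))
#' head(cells)
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "timepoint", "area_um2", "aspect_ratio")
  if (!all(need %in% names(df)))
    stop("cells.csv must have columns: ", paste(need, collapse = ", "))
  if (!all(c("width_um", "length_um") %in% names(df))) {
    wl <- cellWidthLength(df$area_um2, df$aspect_ratio)
    df$width_um <- wl$w; df$length_um <- wl$l
  }
  df
}

#' @rdname io
#' @export
readVesselTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "timepoint", "diameter_um", "length_um")
  if (!all(need %in% names(df)))
    stop("vessels.csv must have columns: ", paste(need, collapse = ", "))
  df
}
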