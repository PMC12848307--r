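#' @import methods
#' @importFrom stats median sd lm coef fft rnorm runif rlnorm approx var cor
#' @importFrom utils read.csv write.csv
#' @useDynLib vesselmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Measurement containers
## ---------------------------------------------------------------------------

#' IntensityProfile: a 1D fluorescence intensity profile across a vessel
#'
#' Positions are in micrometres and must be strictly increasing; intensities
#' are in arbitrary units. Profiles are the input to
#' [diameterFromProfile()], which locates the two wall peaks.
#'
#' @slot positions numeric, µm, strictly increasing.
#' @slot intensities numeric, a.u., same length as `positions`.
#' @slot pixelSize numeric scalar, µm per sample.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", intensities = "numeric",
                 pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@positions) != length(object@intensities))
      return("positions and intensities must have equal length")
    if (length(object@positions) >= 2 && any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      return("pixelSize must be a positive scalar")
    TRUE
  })

#' Construct an IntensityProfile
#'
#' @param positions numeric vector of sample positions (µm), strictly
#'   increasing.
#' @param intensities numeric vector of intensities (a.u.).
#' @param pixelSize sampling interval (µm); defaults to the median spacing of
#'   `positions`.
#' @return An [IntensityProfile-class] object.
#' @examples
#' p <- intensityProfile(seq(0, 10, 0.1), dnorm(seq(0, 10, 0.1), 5, 1))
#' @export
intensityProfile <- function(positions, intensities,
                             pixelSize = stats::median(diff(positions))) {
  new("IntensityProfile", positions = as.numeric(positions),
      intensities = as.numeric(intensities), pixelSize = pixelSize)
}

#' DiameterEstimate: vessel diameter from wall-peak positions
#'
#' @slot diameter numeric, µm.
#' @slot wallPositions numeric length 2, wall-centre positions (µm); `NA`
#'   for averaged estimates.
#' @slot nProfilesAveraged integer, number of profiles averaged.
#' @export
setClass("DiameterEstimate",
  representation(diameter = "numeric", wallPositions = "numeric",
                 nProfilesAveraged = "integer"),
  validity = function(object) {
    if (length(object@diameter) != 1 || object@diameter <= 0)
      return("diameter must be a positive scalar")
    if (object@nProfilesAveraged < 1L)
      return("nProfilesAveraged must be >= 1")
    if (object@nProfilesAveraged == 1L && !anyNA(object@wallPositions) &&
        abs(object@diameter - abs(diff(object@wallPositions))) > 1e-9)
      return("diameter must equal the wall-position separation")
    TRUE
  })

#' IntensityTrace: a time series of fluorescence intensity
#'
#' @slot times numeric, strictly increasing (s or min).
#' @slot values numeric, a.u.
#' @slot channel character label.
#' @export
setClass("IntensityTrace",
  representation(times = "numeric", values = "numeric", channel = "character"),
  validity = function(object) {
    if (length(object@times) != length(object@values))
      return("times and values must have equal length")
    if (length(object@times) >= 2 && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    TRUE
  })

#' Construct an IntensityTrace
#'
#' @param times numeric vector, strictly increasing.
#' @param values numeric vector, same length.
#' @param channel character label (e.g. "actin").
#' @return An [IntensityTrace-class] object.
#' @export
intensityTrace <- function(times, values, channel = "signal") {
  new("IntensityTrace", times = as.numeric(times), values = as.numeric(values),
      channel = channel)
}

#' Kymograph: space x time intensity matrix along a line ROI
#'
#' Rows are positions along the line, columns are time frames. Used to track
#' the gap opened by laser ablation of a cortical actin bundle.
#'
#' @slot matrix numeric matrix, space (rows) x time (columns).
#' @slot pixelSize numeric, µm per row.
#' @slot frameInterval numeric, s per column.
#' @slot ablationFrame integer, column index of the ablation event.
#' @export
setClass("Kymograph",
  representation(matrix = "matrix", pixelSize = "numeric",
                 frameInterval = "numeric", ablationFrame = "integer"),
  validity = function(object) {
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (object@ablationFrame < 1L || object@ablationFrame > ncol(object@matrix))
      return("ablationFrame outside the kymograph time range")
    TRUE
  })

#' Construct a Kymograph
#'
#' @param mat numeric matrix, space (rows) x time (columns).
#' @param pixelSize µm per row.
#' @param frameInterval s per column.
#' @param ablationFrame column index at which ablation occurred.
#' @return A [Kymograph-class] object.
#' @export
kymograph <- function(mat, pixelSize, frameInterval, ablationFrame = 1L) {
  new("Kymograph", matrix = mat, pixelSize = pixelSize,
      frameInterval = frameInterval, ablationFrame = as.integer(ablationFrame))
}

#' OrientationCall: classified cortical actin organisation
#'
#' Angle convention: 0 degrees is the vessel long (axial) axis; 90 degrees is
#' circumferential.
#'
#' @slot label character, one of "C", "M", "L".
#' @slot dominantAngle numeric, degrees relative to the vessel long axis.
#' @slot coherence numeric in [0, 1], structure-tensor anisotropy.
#' @export
setClass("OrientationCall",
  representation(label = "character", dominantAngle = "numeric",
                 coherence = "numeric"),
  validity = function(object) {
    if (!object@label %in% c("C", "M", "L"))
      return("label must be one of C, M, L")
    if (object@coherence < 0 || object@coherence > 1)
      return("coherence must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## Strain containers
## ---------------------------------------------------------------------------

#' IntervalStrains: the six strains of a remodelling interval
#'
#' Vessel, cell and cell-number strain along the radial and axial axes
#' between two timepoints, computed from group means. By construction
#' (1 + vessel strain) = (1 + cell strain) * (1 + number strain) on each axis.
#'
#' @slot interval character length 2, the (t1, t2) labels.
#' @slot epsVesselRadial,epsVesselAxial numeric, from diameter D and length L.
#' @slot epsCellRadial,epsCellAxial numeric, from cell width w and length l.
#' @slot epsNumberRadial,epsNumberAxial numeric, from effective cell numbers.
#' @export
setClass("IntervalStrains",
  representation(interval = "character",
                 epsVesselRadial = "numeric", epsVesselAxial = "numeric",
                 epsCellRadial = "numeric", epsCellAxial = "numeric",
                 epsNumberRadial = "numeric", epsNumberAxial = "numeric"),
  validity = function(object) {
    if (length(object@interval) != 2)
      return("interval must hold the two timepoint labels")
    resR <- (1 + object@epsVesselRadial) -
      (1 + object@epsCellRadial) * (1 + object@epsNumberRadial)
    resA <- (1 + object@epsVesselAxial) -
      (1 + object@epsCellAxial) * (1 + object@epsNumberAxial)
    if (abs(resR) > 1e-9 || abs(resA) > 1e-9)
      return("multiplicative decomposition identity violated")
    TRUE
  })

## ---------------------------------------------------------------------------
## Simulation containers
## ---------------------------------------------------------------------------

#' CortexParams: parameters of the 2D actomyosin cortex model
#'
#' Built by [cortexParams()]; units are µm, s and pN throughout (2D stress in
#' pN/µm). Grouped into named numeric lists mirroring the model's building
#' blocks. The validity method enforces the explicit-Euler stability bound
#' dt < gamma / (4 k_max) and, for the default circumferential configuration,
#' an anchored-filament fraction of at most 1 percent.
#'
#' @slot domain named numeric: Lx, Ly (µm), centralBand (µm).
#' @slot boundaryMode "fixed_walls" or "deformable_membrane".
#' @slot anchoring "longitudinal_membrane", "midline" or "none".
#' @slot counts named numeric: nFilaments, nMotors, nCrosslinkers, nAnchored.
#' @slot filament named numeric: segment rest length, segment-count bounds,
#'   stretch and bend stiffness, anchored filament length.
#' @slot motor named numeric: capture radius, on/off rates, unloaded speed,
#'   stall force, link stiffness and rest length.
#' @slot crosslinker named numeric: on/off rates, stiffness, rest length.
#' @slot membrane named numeric: bead spacing, stretch/bend stiffness,
#'   elastic-foundation stiffness, drag.
#' @slot kinetics named numeric: polymerisation, depolymerisation and
#'   whole-filament turnover rates.
#' @slot numerics named numeric: dt, bead drag, kT, anchor/confinement
#'   stiffness, stress averaging window.
#' @slot preset character, the preset this object was built from.
#' @export
setClass("CortexParams",
  representation(domain = "numeric", boundaryMode = "character",
                 anchoring = "character", counts = "numeric",
                 filament = "numeric", motor = "numeric",
                 crosslinker = "numeric", membrane = "numeric",
                 kinetics = "numeric", numerics = "numeric",
                 preset = "character"),
  validity = function(object) .validCortexParams(object))

#' CortexState: instantaneous state of the cortex simulation
#'
#' @slot time numeric, simulated seconds.
#' @slot filaments list of filaments; each a list with a `beads` matrix
#'   (minus to plus end order), `anchored` flag and anchor bookkeeping.
#' @slot motors numeric matrix (filament index, arc position) x 2 heads;
#'   -1 marks an unbound head.
#' @slot crosslinkers numeric matrix, same layout as motors.
#' @slot membranes list with `y`, `left`, `right` bead coordinates, or empty
#'   in fixed-wall mode.
#' @slot params the [CortexParams-class] the state was built with.
#' @export
setClass("CortexState",
  representation(time = "numeric", filaments = "list", motors = "matrix",
                 crosslinkers = "matrix", membranes = "list",
                 params = "CortexParams"),
  validity = function(object) {
    nf <- length(object@filaments)
    heads <- rbind(object@motors, object@crosslinkers)
    bound <- heads[, c(1, 3), drop = FALSE]
    if (any(bound > nf)) return("bound head references a missing filament")
    for (f in object@filaments)
      if (nrow(f$beads) < 2) return("filament with fewer than 2 beads")
    TRUE
  })

#' CortexTrajectory: recorded time series of a cortex simulation run
#'
#' @slot times numeric, s.
#' @slot stress data.frame of instantaneous virial stress (pN/µm): columns
#'   sxx, syy, sxy for the central region and sxxAll, syyAll, sxyAll for the
#'   whole domain.
#' @slot alignment data.frame: Nx2Central, SCentral, Nx2Peripheral,
#'   SPeripheral (circumferential alignment and segment counts).
#' @slot width numeric, vessel width (µm) per record time.
#' @slot finalState the [CortexState-class] at the end of the run.
#' @slot params the [CortexParams-class] used.
#' @slot seed integer seed of the run.
#' @export
setClass("CortexTrajectory",
  representation(times = "numeric", stress = "data.frame",
                 alignment = "data.frame", width = "numeric",
                 finalState = "CortexState", params = "CortexParams",
                 seed = "integer"),
  validity = function(object) {
    n <- length(object@times)
    if (nrow(object@stress) != n || nrow(object@alignment) != n ||
        length(object@width) != n)
      return("trajectory series must have equal length")
    if (n >= 2 && any(diff(object@times) <= 0))
      return("times must be increasing")
    TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d samples over [%.2f, %.2f] um (px %.3g um)\n",
              length(object@positions), min(object@positions),
              max(object@positions), object@pixelSize))
})

setMethod("show", "DiameterEstimate", function(object) {
  cat(sprintf("DiameterEstimate: %.3f um (n = %d profile%s)\n",
              object@diameter, object@nProfilesAveraged,
              if (object@nProfilesAveraged > 1) "s" else ""))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d px x %d frames (%.3g um/px, %.3g s/frame), ablation at frame %d\n",
              nrow(object@matrix), ncol(object@matrix), object@pixelSize,
              object@frameInterval, object@ablationFrame))
})

setMethod("show", "OrientationCall", function(object) {
  cat(sprintf("OrientationCall: %s (dominant angle %.1f deg, coherence %.3f)\n",
              object@label, object@dominantAngle, object@coherence))
})

setMethod("show", "IntervalStrains", function(object) {
  cat(sprintf("IntervalStrains %s -> %s\n", object@interval[1],
              object@interval[2]))
  m <- rbind(radial = c(object@epsVesselRadial, object@epsCellRadial,
                        object@epsNumberRadial),
             axial = c(object@epsVesselAxial, object@epsCellAxial,
                       object@epsNumberAxial))
  colnames(m) <- c("vessel", "cell", "number")
  print(round(m, 4))
})

setMethod("show", "CortexParams", function(object) {
  cat(sprintf("CortexParams ('%s'): %g x %g um %s, anchoring '%s'\n",
              object@preset, object@domain[["Lx"]], object@domain[["Ly"]],
              object@boundaryMode, object@anchoring))
  cat(sprintf("  %d filaments (%d anchored), %d motors, %d crosslinkers; dt %g s\n",
              object@counts[["nFilaments"]], object@counts[["nAnchored"]],
              object@counts[["nMotors"]], object@counts[["nCrosslinkers"]],
              object@numerics[["dt"]]))
})

setMethod("show", "CortexState", function(object) {
  nb <- sum(vapply(object@filaments, function(f) nrow(f$beads), 0L))
  cat(sprintf("CortexState at t = %.1f s: %d filaments (%d beads), %d motors, %d crosslinkers, %s\n",
              object@time, length(object@filaments), nb, nrow(object@motors),
              nrow(object@crosslinkers), object@params@boundaryMode))
})

setMethod("show", "CortexTrajectory", function(object) {
  cat(sprintf("CortexTrajectory: %d records over %.1f s (seed %d, '%s', anchoring '%s')\n",
              length(object@times), max(object@times), object@seed,
              object@params@boundaryMode, object@params@anchoring))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @param object an object of a vesselmech S4 class.
#' @export
setGeneric("diameter", function(object) standardGeneric("diameter"))

#' Accessors for vesselmech containers
#'
#' Small accessor generics so slots never need to be reached directly:
#' `diameter()` for [DiameterEstimate-class], `positions()` / `intensities()`
#' for [IntensityProfile-class], `orientationLabel()` and `coherence()` for
#' [OrientationCall-class], `strainTable()` for [IntervalStrains-class], and
#' `trajectoryTable()` for [CortexTrajectory-class].
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("diameter", "DiameterEstimate", function(object) object@diameter)

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "IntensityProfile", function(object) object@positions)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "IntensityProfile", function(object)
  object@intensities)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "IntensityTrace", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setMethod("traceTimes", "IntensityTrace", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("orientationLabel", function(object)
  standardGeneric("orientationLabel"))
#' @rdname accessors
#' @export
setMethod("orientationLabel", "OrientationCall", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("coherence", function(object) standardGeneric("coherence"))
#' @rdname accessors
#' @export
setMethod("coherence", "OrientationCall", function(object) object@coherence)

#' @rdname accessors
#' @export
setGeneric("strainTable", function(object) standardGeneric("strainTable"))

#' @rdname accessors
#' @export
setMethod("strainTable", "IntervalStrains", function(object) {
  data.frame(
    interval = paste(object@interval, collapse = "->"),
    axis = c("radial", "axial"),
    eps_vessel = c(object@epsVesselRadial, object@epsVesselAxial),
    eps_cell = c(object@epsCellRadial, object@epsCellAxial),
    eps_number = c(object@epsNumberRadial, object@epsNumberAxial),
    identity_residual = c(
      (1 + object@epsVesselRadial) -
        (1 + object@epsCellRadial) * (1 + object@epsNumberRadial),
      (1 + object@epsVesselAxial) -
        (1 + object@epsCellAxial) * (1 + object@epsNumberAxial)))
})

#' @rdname accessors
#' @export
setGeneric("trajectoryTable", function(object)
  standardGeneric("trajectoryTable"))

#' @rdname accessors
#' @export
setMethod("trajectoryTable", "CortexTrajectory", function(object) {
  cbind(data.frame(t = object@times), object@stress, object@alignment,
        data.frame(width_um = object@width))
})
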