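# R surface of the coarse-grained actomyosin cortex model: parameter presets
# with validity checking, seeded initialisation, stepping/running via the
# compiled core, and the virial-stress / alignment / width readouts.

# validity helper for CortexParams (referenced from the class definition)
.validCortexParams <- function(object) {
  d <- object@domain; n <- object@numerics
  if (any(d[c("Lx", "Ly")] <= 0)) return("domain sides must be > 0")
  if (!object@boundaryMode %in% c("fixed_walls", "deformable_membrane"))
    return("unknown boundaryMode")
  if (!object@anchoring %in% c("longitudinal_membrane", "midline", "none"))
    return("unknown anchoring mode")
  kMax <- max(object@filament[["stretchStiffness"]],
              object@motor[["linkStiffness"]],
              object@crosslinker[["stiffness"]],
              object@numerics[["confinementStiffness"]])
  if (n[["dt"]] >= n[["drag"]] / (4 * kMax))
    return(sprintf("dt = %g s violates the stability bound drag/(4 k_max) = %g s",
                   n[["dt"]], n[["drag"]] / (4 * kMax)))
  cnt <- object@counts
  if (any(cnt < 0)) return("counts must be non-negative")
  if (object@preset == "paper_like" &&
      object@anchoring == "longitudinal_membrane" &&
      cnt[["nAnchored"]] > 0.01 * cnt[["nFilaments"]])
    return("anchored filaments exceed 1% of all filaments in the default circumferential configuration")
  TRUE
}

#' Default parameter sets for the cortex model
#'
#' Two presets sharing the same physical constants: `"paper_like"` (400
#' filaments, 800 motors, 800 crosslinkers in the 8 x 30 µm domain, 4
#' anchored filaments of 2 µm — 1 percent, alternating sides in facing
#' pairs) and `"reduced_test"` (160/320/320 with 6 anchored filaments) for
#' fast ensembles. All values are configurable through `...` overrides
#' using `group.name` keys (e.g. `motor.unloadedSpeed = 0.1`,
#' `counts.nMotors = 400`).
#'
#' Units are µm, s, pN. The explicit-Euler stability bound
#' dt < drag / (4 k_max) is enforced by the class validity.
#'
#' @param preset "paper_like" or "reduced_test".
#' @param boundaryMode "fixed_walls" (phase 1) or "deformable_membrane"
#'   (phase 2).
#' @param anchoring "longitudinal_membrane" (circumferential bundles),
#'   "midline" (longitudinal bundles) or "none".
#' @param ... scalar overrides with `group.name` keys.
#' @return A [CortexParams-class].
#' @examples
#' p <- cortexParams("reduced_test")
#' p
#' @export
cortexParams <- function(preset = c("paper_like", "reduced_test"),
                         boundaryMode = c("fixed_walls",
                                          "deformable_membrane"),
                         anchoring = c("longitudinal_membrane", "midline",
                                       "none"), ...) {
  preset <- match.arg(preset)
  boundaryMode <- match.arg(boundaryMode)
  anchoring <- match.arg(anchoring)
  reduced <- preset == "reduced_test"
  p <- new("CortexParams",
    domain = c(Lx = 8, Ly = 30, centralBand = 8, centralMargin = 2),
    boundaryMode = boundaryMode,
    anchoring = anchoring,
    counts = c(nFilaments = if (reduced) 160 else 400,
               nMotors = if (reduced) 320 else 800,
               nCrosslinkers = if (reduced) 320 else 800,
               nAnchored = if (anchoring == "none") 0
                           else if (reduced) 6 else 4),
    filament = c(segmentRestLength = 0.5, minSegments = 2, maxSegments = 10,
                 stretchStiffness = 100, bendStiffness = 0.5,
                 anchoredLength = 2),
    motor = c(captureRadius = 0.25, onRate = 20, offRate = 0.1,
              unloadedSpeed = 0.3, stallForce = 4, linkStiffness = 20,
              linkRestLength = 0.1, anchorAffinity = 5),
    crosslinker = c(onRate = 10, offRate = 0.05, stiffness = 20,
                    restLength = 0.1, alignStiffness = 2),
    membrane = c(spacing = 0.5, stretchStiffness = 20, bendStiffness = 1,
                 foundationStiffness = 0.3, drag = 90),
    kinetics = c(polymerRate = 0.1, depolymerRate = 0.1,
                 turnoverRate = 1 / 240),
    numerics = c(dt = 1e-3, drag = 0.5, kT = 0.02,
                 confinementStiffness = 20, thermalNoise = 1,
                 stressWindow = 30),
    preset = preset)
  dots <- list(...)
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% slotNames("CortexParams"))
      stop("unknown parameter key '", key, "' (use group.name)")
    grp <- slot(p, parts[1])
    if (!parts[2] %in% names(grp))
      stop("unknown parameter '", parts[2], "' in group '", parts[1], "'")
    grp[[parts[2]]] <- dots[[key]]
    slot(p, parts[1]) <- grp
  }
  validObject(p)
  p
}

# flatten a CortexParams into the list the C++ core expects
.paramsForCpp <- function(p) {
  list(Lx = p@domain[["Lx"]], Ly = p@domain[["Ly"]],
       centralBand = p@domain[["centralBand"]],
       centralMargin = p@domain[["centralMargin"]],
       boundary = if (p@boundaryMode == "deformable_membrane") 1L else 0L,
       segL = p@filament[["segmentRestLength"]],
       kStretch = p@filament[["stretchStiffness"]],
       kBend = p@filament[["bendStiffness"]],
       minSeg = as.integer(p@filament[["minSegments"]]),
       maxSeg = as.integer(p@filament[["maxSegments"]]),
       capR = p@motor[["captureRadius"]],
       mOn = p@motor[["onRate"]], mOff = p@motor[["offRate"]],
       v0 = p@motor[["unloadedSpeed"]], fStall = p@motor[["stallForce"]],
       kLink = p@motor[["linkStiffness"]],
       linkRest = p@motor[["linkRestLength"]],
       anchorAffinity = p@motor[["anchorAffinity"]],
       xOn = p@crosslinker[["onRate"]], xOff = p@crosslinker[["offRate"]],
       kXl = p@crosslinker[["stiffness"]],
       xlRest = p@crosslinker[["restLength"]],
       kAlign = p@crosslinker[["alignStiffness"]],
       memSpacing = p@membrane[["spacing"]],
       kMemStretch = p@membrane[["stretchStiffness"]],
       kMemBend = p@membrane[["bendStiffness"]],
       kFound = p@membrane[["foundationStiffness"]],
       memDrag = p@membrane[["drag"]],
       polyRate = p@kinetics[["polymerRate"]],
       depolyRate = p@kinetics[["depolymerRate"]],
       turnRate = p@kinetics[["turnoverRate"]],
       dt = p@numerics[["dt"]], drag = p@numerics[["drag"]],
       kT = p@numerics[["kT"]],
       kConf = p@numerics[["confinementStiffness"]],
       noise = p@numerics[["thermalNoise"]] > 0)
}

#' Initialise a cortex simulation state
#'
#' Free filaments are placed uniformly at random with uniform orientations
#' (straight, 2-6 segments of 0.5 µm). Anchored filaments of the configured
#' length are clamped by their plus-end base segment (sarcomere-like
#' anchorage, so plus-directed motors load anchored chains with tension):
#' in `longitudinal_membrane` mode at membrane beads (or wall points under
#' fixed walls) on alternating sides in facing pairs within the central
#' y-band, oriented inward along x; in `midline` mode at fixed points on
#' the vertical midline, oriented along y with alternating polarity.
#' Motors and crosslinkers start unbound. Deterministic per seed.
#'
#' @param params a [CortexParams-class].
#' @param seed integer seed.
#' @return A [CortexState-class].
#' @export
initCortex <- function(params, seed = 1L) {
  stopifnot(is(params, "CortexParams"))
  Lx <- params@domain[["Lx"]]; Ly <- params@domain[["Ly"]]
  band <- params@domain[["centralBand"]]
  segL <- params@filament[["segmentRestLength"]]
  nFil <- as.integer(params@counts[["nFilaments"]])
  nAnch <- as.integer(params@counts[["nAnchored"]])
  if (params@anchoring == "none") nAnch <- 0L
  minSeg <- params@filament[["minSegments"]]
  maxSeg <- params@filament[["maxSegments"]]
  anchSeg <- round(params@filament[["anchoredLength"]] / segL)
  nFree <- nFil - nAnch
  if (nFree < 0) stop("overcrowded initialization: nAnchored > nFilaments")
  areaPerFil <- Lx * Ly / max(1, nFil)
  if (areaPerFil < 0.05)
    stop("overcrowded initialization: too many filaments for the domain")

  deform <- params@boundaryMode == "deformable_membrane"
  membranes <- list()
  if (deform) {
    y <- seq(0, Ly, by = params@membrane[["spacing"]])
    membranes <- list(y = y, left = rep(0, length(y)),
                      right = rep(Lx, length(y)))
  }

  withLocalSeed(seed, {
    fils <- vector("list", nFil)
    mkFree <- function() {
      ns <- sample(seq(minSeg, maxSeg), 1)
      repeat {
        th <- runif(1, 0, 2 * pi)
        half <- ns * segL / 2
        cx <- runif(1, 0.5, Lx - 0.5)
        cy <- runif(1, 0, Ly)
        s <- (seq_len(ns + 1) - 1 - ns / 2) * segL
        bx <- cx + s * cos(th)
        if (all(bx > 0.1 & bx < Lx - 0.1))
          return(list(beads = cbind(bx, cy + s * sin(th)), anchored = FALSE,
                      memSide = -1L, memIdx = 0L, anchor = c(0, 0)))
      }
    }
    for (i in seq_len(nFree)) fils[[i]] <- mkFree()

    if (nAnch > 0) {
      y0 <- (Ly - band) / 2
      # facing pairs: consecutive anchors alternate sides at the same y, so
      # a circumferential bundle can bridge the two walls straight across
      nPairs <- ceiling(nAnch / 2)
      ys <- rep(y0 + (seq_len(nPairs) - 0.5) * band / nPairs, each = 2)[
        seq_len(nAnch)]
      for (k in seq_len(nAnch)) {
        if (params@anchoring == "longitudinal_membrane") {
          side <- (k - 1L) %% 2L              # 0 left, 1 right
          x0 <- if (side == 0L) 0 else Lx
          dir <- if (side == 0L) 1 else -1
          # minus end inward, plus end (last bead) clamped at the wall:
          # sarcomere-like anchorage, so plus-directed motors pull inward
          # network material toward the wall and load the chain with tension
          bx <- x0 + dir * (anchSeg:0) * segL
          by <- rep(ys[k], anchSeg + 1)
          if (deform) {
            idx <- which.min(abs(membranes$y - ys[k]))
            by <- rep(membranes$y[idx], anchSeg + 1)
            fils[[nFree + k]] <- list(beads = cbind(bx, by), anchored = TRUE,
                                      memSide = side, memIdx = as.integer(idx),
                                      anchor = c(x0, by[1]))
          } else {
            fils[[nFree + k]] <- list(beads = cbind(bx, by), anchored = TRUE,
                                      memSide = -1L, memIdx = 0L,
                                      anchor = c(x0, ys[k]))
          }
        } else {                              # midline, oriented along y
          dir <- if (k %% 2 == 0) 1 else -1
          bx <- rep(Lx / 2, anchSeg + 1)
          # plus end (last bead) clamped at the midline pin
          by <- ys[k] + dir * (anchSeg:0) * segL
          fils[[nFree + k]] <- list(beads = cbind(bx, by), anchored = TRUE,
                                    memSide = -1L, memIdx = 0L,
                                    anchor = c(Lx / 2, ys[k]))
        }
      }
    }
    unbound <- function(n) {
      m <- matrix(0, n, 4)
      colnames(m) <- c("f1", "s1", "f2", "s2")
      m
    }
    new("CortexState", time = 0, filaments = fils,
        motors = unbound(as.integer(params@counts[["nMotors"]])),
        crosslinkers = unbound(as.integer(params@counts[["nCrosslinkers"]])),
        membranes = membranes, params = params)
  })
}

# CortexState -> plain list for the C++ core
.stateForCpp <- function(state) {
  list(time = state@time, filaments = state@filaments, motors = state@motors,
       crosslinkers = state@crosslinkers, membranes = state@membranes)
}

.stateFromCpp <- function(lst, params) {
  new("CortexState", time = lst$time, filaments = lst$filaments,
      motors = lst$motors, crosslinkers = lst$crosslinkers,
      membranes = if (length(lst$membranes) > 0) lst$membranes else list(),
      params = params)
}

#' Advance a cortex state by a number of steps
#'
#' One step is: force evaluation, overdamped explicit-Euler bead motion with
#' optional thermal kicks, then stochastic kinetics (binding/unbinding,
#' motor stepping, polymerisation/depolymerisation, turnover) in fixed
#' order, with rates converted to per-step probabilities 1 - exp(-rate dt).
#'
#' @param state a [CortexState-class].
#' @param nSteps number of dt steps.
#' @param seed integer seed for the step's stochastic events.
#' @return The advanced [CortexState-class].
#' @export
stepCortex <- function(state, nSteps = 1L, seed = 1L) {
  stopifnot(is(state, "CortexState"))
  res <- cpp_step_cortex(.stateForCpp(state), .paramsForCpp(state@params),
                         as.integer(seed), as.integer(nSteps))
  if (res$diverged) stop("unstable step; reduce dt")
  .stateFromCpp(res$state, state@params)
}

#' Run a cortex simulation and record a trajectory
#'
#' Initialises from `params` (or continues `state`), advances for
#' `duration` simulated seconds and records, every `recordEvery` seconds,
#' the instantaneous virial stress (central region and whole domain),
#' circumferential alignment Nx^2 with segment counts (central and
#' peripheral), and the vessel width in the central band. Stress series are
#' also returned smoothed with the sliding window configured in
#' `numerics.stressWindow` (the `<.>` of the virial formula).
#'
#' @param params a [CortexParams-class].
#' @param duration simulated seconds.
#' @param recordEvery recording interval (s); default 2.
#' @param seed integer seed (initialisation and dynamics).
#' @param state optional [CortexState-class] to continue from instead of
#'   initialising.
#' @return A [CortexTrajectory-class]. The `stress` slot holds the
#'   window-averaged series; raw instantaneous series are in
#'   `attr(trajectory, "rawStress")`.
#' @examples
#' \donttest{
#' p <- cortexParams("reduced_test")
#' tr <- runCortex(p, duration = 30, recordEvery = 2, seed = 1)
#' }
#' @export
runCortex <- function(params, duration, recordEvery = 2, seed = 1L,
                      state = NULL) {
  stopifnot(is(params, "CortexParams"), duration > 0, recordEvery > 0)
  if (is.null(state)) state <- initCortex(params, seed = seed)
  res <- cpp_run_cortex(.stateForCpp(state), .paramsForCpp(params),
                        as.integer(seed), duration, recordEvery)
  if (res$diverged) stop("unstable step; reduce dt")
  win <- max(1L, round(params@numerics[["stressWindow"]] / recordEvery))
  smooth <- function(v) rollMean(v, win)
  stress <- data.frame(sxx = smooth(res$sxx), syy = smooth(res$syy),
                       sxy = smooth(res$sxy), sxxAll = smooth(res$sxxAll),
                       syyAll = smooth(res$syyAll),
                       sxyAll = smooth(res$sxyAll))
  align <- data.frame(Nx2Central = res$nx2Central, SCentral = res$sCentral,
                      Nx2Peripheral = res$nx2Peripheral,
                      SPeripheral = res$sPeripheral)
  traj <- new("CortexTrajectory", times = res$times, stress = stress,
              alignment = align, width = res$width,
              finalState = .stateFromCpp(res$state, params), params = params,
              seed = as.integer(seed))
  attr(traj, "rawStress") <- data.frame(sxx = res$sxx, syy = res$syy,
                                        sxy = res$sxy, sxxAll = res$sxxAll,
                                        syyAll = res$syyAll,
                                        sxyAll = res$sxyAll)
  attr(traj, "anchorLoad") <- res$anchorLoad
  traj
}

#' Pair-force ledger of a state
#'
#' One row per interacting pair in the last force evaluation: separation
#' components (`rx`, `ry`; minimum image in y), force on the second member
#' (`fx`, `fy`) and the pair midpoint (`mx`, `my`). Three-body bending terms
#' are decomposed into equal-and-opposite centre-to-neighbour pairs.
#'
#' @param state a [CortexState-class].
#' @return A numeric matrix with columns rx, ry, fx, fy, mx, my.
#' @export
pairForces <- function(state) {
  stopifnot(is(state, "CortexState"))
  cpp_pair_forces(.stateForCpp(state), .paramsForCpp(state@params))
}

#' Virial stress tensor over a region
#'
#' Computes sigma_ab = (1/A) * sum over pairs of f_ij,a * r_ij,b, restricted
#' to pairs whose midpoint lies in `region`, with tensile contributions
#' positive. Accepts either a [CortexState-class] (ledger computed via
#' [pairForces()]) or a ledger matrix directly with an explicit `area`.
#'
#' @param x a [CortexState-class] or a ledger matrix (columns rx, ry, fx,
#'   fy, mx, my).
#' @param region numeric length 4 `c(x0, x1, y0, y1)` or `NULL` for the
#'   whole domain.
#' @param area region area (µm²); required for ledger input, derived from
#'   the domain/region for state input.
#' @return Named numeric: sxx, syy, sxy (pN/µm).
#' @examples
#' led <- cbind(rx = 1, ry = 0, fx = 1, fy = 0, mx = 0.5, my = 0.5)
#' computeStress(led, area = 1)  # sxx = 1
#' @export
computeStress <- function(x, region = NULL, area = NULL) {
  if (is(x, "CortexState")) {
    led <- pairForces(x)
    d <- x@params@domain
    if (is.null(region)) region <- c(0, d[["Lx"]], 0, d[["Ly"]])
    if (is.null(area)) area <- (region[2] - region[1]) *
        (region[4] - region[3])
  } else {
    led <- x
    if (is.null(area)) stop("area must be given for ledger input")
  }
  if (!is.null(region)) {
    keep <- led[, "mx"] >= region[1] & led[, "mx"] <= region[2] &
      led[, "my"] >= region[3] & led[, "my"] <= region[4]
    led <- led[keep, , drop = FALSE]
  }
  if (nrow(led) == 0) stop("no pairs in region")
  c(sxx = sum(led[, "fx"] * led[, "rx"]) / area,
    syy = sum(led[, "fy"] * led[, "ry"]) / area,
    sxy = sum(0.5 * (led[, "fx"] * led[, "ry"] +
                       led[, "fy"] * led[, "rx"])) / area)
}

#' Circumferential alignment of a region
#'
#' Nx^2 = sum over filament segments in the region of the squared x
#' component of the unit segment orientation; equals the segment count S
#' when every segment is circumferential, and S/2 in expectation for an
#' isotropic network. Segments are assigned by midpoint; Nx^2 + Ny^2 = S
#' exactly.
#'
#' @param state a [CortexState-class].
#' @param region `c(x0, x1, y0, y1)` or `NULL` for the whole domain.
#' @return A list: `Nx2`, `Ny2`, `S` (segment count).
#' @export
computeAlignment <- function(state, region = NULL) {
  stopifnot(is(state, "CortexState"))
  d <- state@params@domain
  Ly <- d[["Ly"]]
  if (is.null(region)) region <- c(0, d[["Lx"]], 0, Ly)
  nx2 <- 0; s <- 0L
  for (f in state@filaments) {
    b <- f$beads
    for (i in seq_len(nrow(b) - 1)) {
      dx <- b[i + 1, 1] - b[i, 1]; dy <- b[i + 1, 2] - b[i, 2]
      r2 <- dx^2 + dy^2
      if (r2 == 0) next
      mx <- (b[i, 1] + b[i + 1, 1]) / 2
      my <- ((b[i, 2] + b[i + 1, 2]) / 2) %% Ly
      if (mx >= region[1] && mx <= region[2] && my >= region[3] &&
          my <= region[4]) {
        nx2 <- nx2 + unname(dx^2 / r2)
        s <- s + 1L
      }
    }
  }
  # Ny2 as the exact complement: Nx2 + Ny2 = S holds to the last bit
  list(Nx2 = nx2, Ny2 = s - nx2, S = as.numeric(s))
}

#' Vessel width of a state
#'
#' Mean left-right membrane gap over the y-range of `region` (membranes
#' linearly interpolated in y); under fixed walls the domain width Lx is
#' returned. Errors if the membranes cross.
#'
#' @param state a [CortexState-class].
#' @param region `c(x0, x1, y0, y1)` or `NULL` for the whole domain; only
#'   the y-range is used.
#' @return Width in µm.
#' @export
vesselWidth <- function(state, region = NULL) {
  stopifnot(is(state, "CortexState"))
  d <- state@params@domain
  if (state@params@boundaryMode == "fixed_walls" ||
      length(state@membranes) == 0)
    return(unname(d[["Lx"]]))
  m <- state@membranes
  if (is.null(region)) region <- c(0, d[["Lx"]], 0, d[["Ly"]])
  yy <- seq(max(region[3], min(m$y)), min(region[4], max(m$y)),
            length.out = 201)
  xl <- approx(m$y, m$left, yy)$y
  xr <- approx(m$y, m$right, yy)$y
  if (any(xr <= xl)) stop("membrane collision")
  mean(xr - xl)
}

#' Write a simulation run to disk
#'
#' Summary time-series CSV (t, stress components, alignment, width), a
#' per-bead particle-table CSV of the final state, and a JSON provenance
#' record echoing every parameter and the seed.
#'
#' @param traj a [CortexTrajectory-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRun <- function(traj, dir) {
  stopifnot(is(traj, "CortexTrajectory"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(trajectoryTable(traj), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  st <- traj@finalState
  rows <- do.call(rbind, lapply(seq_along(st@filaments), function(i) {
    b <- st@filaments[[i]]$beads
    data.frame(entity_type = "filament", entity_id = i,
               bead_index = seq_len(nrow(b)), x_um = b[, 1], y_um = b[, 2],
               anchored = st@filaments[[i]]$anchored)
  }))
  utils::write.csv(rows, file.path(dir, "particles.csv"), row.names = FALSE)
  p <- traj@params
  prov <- list(seed = traj@seed, preset = p@preset,
               boundaryMode = p@boundaryMode, anchoring = p@anchoring,
               domain = as.list(p@domain), counts = as.list(p@counts),
               filament = as.list(p@filament), motor = as.list(p@motor),
               crosslinker = as.list(p@crosslinker),
               membrane = as.list(p@membrane), kinetics = as.list(p@kinetics),
               numerics = as.list(p@numerics),
               duration = max(traj@times))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
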