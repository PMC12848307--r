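# The strain decomposition: vessel, cell and cell-number strain along the
# radial and axial vessel axes between two timepoints. Strains are computed
# from group means (cells are not tracked across days), and the effective
# cell numbers are recomputed from the mean geometry at each timepoint, which
# makes the multiplicative decomposition identities exact:
#   (1 + eps_D) = (1 + eps_w) (1 + eps_Nrad),
#   (1 + eps_L) = (1 + eps_l) (1 + eps_Nax).

#' Strain of a positive quantity between two timepoints
#'
#' For a geometric quantity X (vessel diameter D, length L, cell width w,
#' cell length l, effective cell number N_eff), the strain between two
#' timepoints is eps_X = (X2 - X1) / X1. Vectorised; scale invariant;
#' satisfies (1 + eps(X1 -> X2)) * (1 + eps(X2 -> X1)) = 1.
#'
#' @param x1 reference value(s), > 0.
#' @param x2 later value(s), same units.
#' @return Dimensionless strain(s).
#' @examples
#' strain(10, 8)  # -0.2
#' @export
strain <- function(x1, x2) {
  if (any(!is.finite(x1)) || any(x1 <= 0))
    stop("invalid reference value: x1 must be > 0")
  (x2 - x1) / x1
}

#' Summarise a vessel/cell group at one timepoint
#'
#' Arithmetic means of diameter, length, cell width and cell length over all
#' vessels and cells measured at `timepoint` — the population averages behind
#' a per-stage strain analysis.
#'
#' @param vessels vessel table with columns `vessel_id`, `timepoint`,
#'   `diameter_um`, `length_um` (see [readVesselTable()]).
#' @param cells cell table with columns `cell_id`, `timepoint`, `area_um2`,
#'   `aspect_ratio` (width/length derived if absent; see [readCellTable()]).
#' @param timepoint label to summarise.
#' @return A one-row data.frame: `timepoint`, `mean_D`, `mean_L`, `mean_w`,
#'   `mean_l`, `n_vessels`, `n_cells`.
#' @export
summarizeGroup <- function(vessels, cells, timepoint) {
  v <- vessels[vessels$timepoint == timepoint, , drop = FALSE]
  cl <- cells[cells$timepoint == timepoint, , drop = FALSE]
  if (nrow(v) == 0 || nrow(cl) == 0)
    stop("no observations at timepoint '", timepoint, "'")
  if (!all(c("width_um", "length_um") %in% names(cl))) {
    wl <- cellWidthLength(cl$area_um2, cl$aspect_ratio)
    cl$width_um <- wl$w; cl$length_um <- wl$l
  }
  data.frame(timepoint = timepoint,
             mean_D = mean(v$diameter_um), mean_L = mean(v$length_um),
             mean_w = mean(cl$width_um), mean_l = mean(cl$length_um),
             n_vessels = nrow(v), n_cells = nrow(cl))
}

#' Decompose an interval into vessel, cell and cell-number strains
#'
#' Computes the six strains between two group summaries. The effective cell
#' number at each timepoint is recomputed from that timepoint's mean D, L,
#' w, l (not averaged per cell), which guarantees the exact multiplicative
#' identity (1 + vessel strain) = (1 + cell strain)(1 + number strain) on
#' both axes.
#'
#' @param s1,s2 group summaries from [summarizeGroup()] (one-row data.frames).
#' @return An [IntervalStrains-class].
#' @examples
#' s1 <- data.frame(timepoint = "t1", mean_D = 10, mean_L = 60, mean_w = 2,
#'                  mean_l = 20, n_vessels = 5, n_cells = 10)
#' s2 <- transform(s1, timepoint = "t2", mean_D = 8, mean_w = 1.8)
#' decomposeInterval(s1, s2)
#' @export
decomposeInterval <- function(s1, s2) {
  for (s in list(s1, s2))
    stopIfNotPositive(s$mean_D, s$mean_L, s$mean_w, s$mean_l,
                      msg = "invalid reference value: group means must be > 0")
  n1 <- effectiveCellNumbers(s1$mean_D, s1$mean_L, s1$mean_w, s1$mean_l)
  n2 <- effectiveCellNumbers(s2$mean_D, s2$mean_L, s2$mean_w, s2$mean_l)
  new("IntervalStrains",
      interval = c(as.character(s1$timepoint), as.character(s2$timepoint)),
      epsVesselRadial = strain(s1$mean_D, s2$mean_D),
      epsVesselAxial = strain(s1$mean_L, s2$mean_L),
      epsCellRadial = strain(s1$mean_w, s2$mean_w),
      epsCellAxial = strain(s1$mean_l, s2$mean_l),
      epsNumberRadial = strain(n1$radial, n2$radial),
      epsNumberAxial = strain(n1$axial, n2$axial))
}

#' Strain decomposition across consecutive timepoints
#'
#' Convenience wrapper: summarises each timepoint and decomposes every
#' consecutive interval.
#'
#' @inheritParams summarizeGroup
#' @param timepoints ordered labels; default: order of appearance in
#'   `vessels`.
#' @return A named list of [IntervalStrains-class], one per interval.
#' @export
strainAnalysis <- function(vessels, cells,
                           timepoints = unique(vessels$timepoint)) {
  sums <- lapply(timepoints, function(tp) summarizeGroup(vessels, cells, tp))
  out <- list()
  for (k in seq_len(length(timepoints) - 1)) {
    st <- decomposeInterval(sums[[k]], sums[[k + 1]])
    out[[paste(timepoints[k], timepoints[k + 1], sep = "->")]] <- st
  }
  out
}

#' Label the remodelling mechanism per axis
#'
#' Descriptive tags for how cell deformation and cell rearrangement relate to
#' the net vessel change on each axis: a component whose strain exceeds the
#' dead-band `tol` and shares the vessel strain's sign is "contributing", one
#' with the opposite sign is "opposing", and anything within the dead-band is
#' "neutral". For example, a constriction with negative cell strain and
#' negative number strain is driven by both cell narrowing and rearrangement,
#' while a constriction with positive cell strain is achieved by
#' rearrangement opposed by cell widening.
#'
#' @param strains an [IntervalStrains-class].
#' @param tol dead-band on the strain magnitude; default 0.02.
#' @return A list with elements `radial` and `axial`, each holding `vessel`
#'   ("constriction"/"expansion"/"stable" radially,
#'   "shortening"/"elongation"/"stable" axially) and the `cell` / `number`
#'   tags.
#' @export
labelMechanism <- function(strains, tol = 0.02) {
  stopifnot(is(strains, "IntervalStrains"))
  tag <- function(eps, epsVessel) {
    if (abs(eps) <= tol) "neutral"
    else if (abs(epsVessel) <= tol) "compensated"
    else if (sign(eps) == sign(epsVessel)) "contributing"
    else "opposing"
  }
  axis <- function(epsV, epsC, epsN, words) {
    list(vessel = if (abs(epsV) <= tol) "stable"
                  else if (epsV < 0) words[1] else words[2],
         cell = tag(epsC, epsV), number = tag(epsN, epsV))
  }
  list(radial = axis(strains@epsVesselRadial, strains@epsCellRadial,
                     strains@epsNumberRadial, c("constriction", "expansion")),
       axial = axis(strains@epsVesselAxial, strains@epsCellAxial,
                    strains@epsNumberAxial, c("shortening", "elongation")))
}

#' Write interval strains to CSV
#'
#' One row per interval and axis with the three strains and the
#' decomposition identity residual.
#'
#' @param strains an [IntervalStrains-class] or a list of them.
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
writeStrainTable <- function(strains, path) {
  if (is(strains, "IntervalStrains")) strains <- list(strains)
  df <- do.call(rbind, lapply(strains, strainTable))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
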