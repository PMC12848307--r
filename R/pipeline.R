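# End-to-end synthetic study: generate -> measure -> strain -> recoil ->
# classify -> simulate -> analyze, with every artifact written to disk plus
# a JSON provenance record. This orchestrator (with the exported module
# functions) is the package's entry point; all outputs are reproducible from
# the provenance record.

#' Run the full synthetic demonstration pipeline
#'
#' Exercises every module on seeded synthetic data: vessel-wall profiles are
#' generated and measured ([diameterFromProfile()]); cell/vessel tables are
#' generated, summarised and decomposed into strains
#' ([strainAnalysis()], written to `strains.csv`); a synthetic ablation
#' kymograph is traced and its recoil velocity estimated (`recoil.csv`);
#' oriented textures are classified (`orientation.csv`); and a short
#' reduced-preset cortex simulation is run, summarised (`sim_summary.csv`)
#' and written with its own provenance. A `provenance.json` in `outDir`
#' records the seed and the per-stage parameters.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param simDuration simulated seconds for the demonstration run; default
#'   240 (kept short; see the vignette for study-scale runs).
#' @return Named list of the per-stage results, invisibly; files in
#'   `outDir`.
#' @examples
#' \donttest{
#' res <- demoPipeline(file.path(tempdir(), "demo"), seed = 1)
#' }
#' @export
demoPipeline <- function(outDir, seed = 1L, simDuration = 240) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- as.integer(seed)

  # vessel diameter from repeated noisy wall profiles
  profSeeds <- seed * 100L + 1:5
  est <- lapply(profSeeds, function(s) {
    g <- genWallProfile(wallCenters = c(2, 8), wallShape = "gaussian",
                        wallHalfwidth = 0.3, noiseSd = 0.03, seed = s)
    diameterFromProfile(g$profile)
  })
  dia <- meanDiameter(est)

  # cell shape tables -> strain decomposition
  tab <- genCellShapeTable(nCells = 60, noiseCv = 0.08, seed = seed + 1L)
  writeCellTable(tab$cells, file.path(outDir, "cells.csv"))
  writeVesselTable(tab$vessels, file.path(outDir, "vessels.csv"))
  strains <- strainAnalysis(tab$vessels, tab$cells)
  writeStrainTable(strains, file.path(outDir, "strains.csv"))

  # ablation kymograph -> recoil velocity (three ROIs emulated by three
  # noise realisations of the same ablation)
  rois <- vapply(1:3, function(k) {
    g <- genKymograph(trueVelocity = 0.5, noiseSd = 0.04,
                      seed = seed * 10L + k)
    gap <- traceGapEdges(g$kymograph)
    tt <- (seq_along(gap) - 1) * g$kymograph@frameInterval
    recoilVelocity(gap, tt, window = 10)$velocity
  }, numeric(1))
  recoil <- meanRecoil(rois)
  utils::write.csv(
    data.frame(roi = 1:3, velocity_um_s = recoil$perRoiVelocity,
               mean_velocity_um_s = recoil$meanVelocity),
    file.path(outDir, "recoil.csv"), row.names = FALSE)

  # oriented textures -> classification
  calls <- lapply(c("C", "M", "L"), function(lb) {
    tex <- genOrientedTexture(lb, angleJitterSd = 5, noiseSd = 0.2,
                              seed = seed + match(lb, c("C", "M", "L")))
    classifyOrientation(tex$image)
  })
  utils::write.csv(
    data.frame(truth = c("C", "M", "L"),
               call = vapply(calls, orientationLabel, character(1)),
               coherence = vapply(calls, coherence, numeric(1))),
    file.path(outDir, "orientation.csv"), row.names = FALSE)

  # short cortex simulation + summary
  p <- cortexParams("reduced_test", boundaryMode = "deformable_membrane")
  traj <- runCortex(p, duration = simDuration, recordEvery = 2, seed = seed)
  writeRun(traj, file.path(outDir, "sim"))
  simSum <- summarizeRun(traj, minDuration = 30, burnIn = 30,
                         maxLag = simDuration / 3)
  utils::write.csv(simSum, file.path(outDir, "sim_summary.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed, stages = c("diameter", "strain", "recoil",
                                 "orientation", "simulation"),
         simDuration = simDuration,
         package = "vesselmech",
         version = as.character(utils::packageVersion("vesselmech"))),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(diameter = dia, strains = strains, recoil = recoil,
                 orientation = calls, simSummary = simSum))
}
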