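# Strain arithmetic, group summaries, the multiplicative decomposition and
# mechanism labels.

test_that("strain is the relative change and satisfies exact relations", {
  expect_equal(strain(10, 8), -0.2)
  expect_equal(strain(57.3, 57.3), 0)
  expect_equal(strain(7.3 * 10, 7.3 * 8), strain(10, 8))   # scale invariance
  # exact inverse relation (not antisymmetry, which only holds to 1st order)
  x1 <- 8.2; x2 <- 11.7
  expect_equal((1 + strain(x1, x2)) * (1 + strain(x2, x1)), 1,
               tolerance = 1e-12)
  expect_error(strain(0, 1), "invalid reference")
  expect_error(strain(-2, 1), "invalid reference")
})

test_that("group summaries are plain means, idempotent under duplication", {
  g <- genCellShapeTable(nCells = 6, noiseCv = 0.1, seed = 4)
  s <- summarizeGroup(g$vessels, g$cells, "2dpf")
  v <- g$vessels[g$vessels$timepoint == "2dpf", ]
  expect_equal(s$mean_D, mean(v$diameter_um))
  expect_equal(s$n_cells, 6)
  sdup <- summarizeGroup(rbind(g$vessels, g$vessels),
                         rbind(g$cells, g$cells), "2dpf")
  expect_equal(sdup$mean_D, s$mean_D)
  expect_equal(sdup$mean_w, s$mean_w)
  expect_error(summarizeGroup(g$vessels, g$cells, "9dpf"), "no observations")
})

test_that("interval decomposition matches the direct arithmetic oracle", {
  s1 <- data.frame(timepoint = "t1", mean_D = 10, mean_L = 60, mean_w = 2,
                   mean_l = 20, n_vessels = 5, n_cells = 10)
  s2 <- data.frame(timepoint = "t2", mean_D = 8, mean_L = 60, mean_w = 1.8,
                   mean_l = 20, n_vessels = 5, n_cells = 10)
  st <- decomposeInterval(s1, s2)
  expect_equal(st@epsVesselRadial, -0.2)
  expect_equal(st@epsCellRadial, -0.1)
  expect_equal(st@epsNumberRadial, -1 / 9, tolerance = 1e-12)
  # the oracle identity: 0.9 * (8/9) = 0.8
  expect_equal((1 + st@epsCellRadial) * (1 + st@epsNumberRadial),
               1 + st@epsVesselRadial, tolerance = 1e-12)
  # equal summaries give all-zero strains
  st0 <- decomposeInterval(s1, transform(s1, timepoint = "t2"))
  expect_equal(strainTable(st0)$eps_vessel, c(0, 0))
  expect_equal(strainTable(st0)$eps_cell, c(0, 0))
  expect_equal(strainTable(st0)$eps_number, c(0, 0))
})

test_that("decomposition identities hold to 1e-12 on random summaries", {
  set.seed(11)
  for (k in 1:200) {
    s1 <- data.frame(timepoint = "a", mean_D = runif(1, 3, 12),
                     mean_L = runif(1, 30, 90), mean_w = runif(1, 1, 6),
                     mean_l = runif(1, 8, 40), n_vessels = 3, n_cells = 5)
    s2 <- data.frame(timepoint = "b", mean_D = runif(1, 3, 12),
                     mean_L = runif(1, 30, 90), mean_w = runif(1, 1, 6),
                     mean_l = runif(1, 8, 40), n_vessels = 3, n_cells = 5)
    st <- strainTable(decomposeInterval(s1, s2))
    expect_lt(max(abs(st$identity_residual)), 1e-12)
  }
})

test_that("prescribed strains are recovered from synthetic tables", {
  g0 <- genCellShapeTable(nCells = 10, noiseCv = 0, seed = 2)
  rec <- strainAnalysis(g0$vessels, g0$cells)
  for (nm in names(rec)) {
    expect_equal(strainTable(rec[[nm]])$eps_vessel,
                 strainTable(g0$truth$strains[[nm]])$eps_vessel,
                 tolerance = 1e-10)
    expect_equal(strainTable(rec[[nm]])$eps_cell,
                 strainTable(g0$truth$strains[[nm]])$eps_cell,
                 tolerance = 1e-10)
  }
  # noisy: recovered radial vessel strain within 3 SE of prescription
  g <- genCellShapeTable(nCells = 200, nVessels = 200, noiseCv = 0.1,
                         seed = 3)
  rec <- strainAnalysis(g$vessels, g$cells)[[1]]
  truth <- g$truth$strains[[1]]
  seRel <- 0.1 / sqrt(200)                 # relative SE of each group mean
  seStrain <- sqrt(2) * seRel * (1 + abs(truth@epsVesselRadial))
  expect_lt(abs(rec@epsVesselRadial - truth@epsVesselRadial), 3 * seStrain)
})

test_that("mechanism labels follow the sign/dead-band rule table", {
  mk <- function(vr, cr, nr) new("IntervalStrains", interval = c("a", "b"),
    epsVesselRadial = vr, epsCellRadial = cr, epsNumberRadial = nr,
    epsVesselAxial = (1 + 0) * (1 + 0) - 1, epsCellAxial = 0,
    epsNumberAxial = 0)
  # both cell narrowing and rearrangement contribute to constriction
  st <- mk((1 - 0.1) * (1 - 0.11) - 1, -0.1, -0.11)
  lab <- labelMechanism(st)
  expect_equal(lab$radial$vessel, "constriction")
  expect_equal(lab$radial$cell, "contributing")
  expect_equal(lab$radial$number, "contributing")
  # constriction via rearrangement opposed by cell widening
  st2 <- mk((1 + 0.1) * (1 - 0.3) - 1, +0.1, -0.3)
  lab2 <- labelMechanism(st2)
  expect_lt(st2@epsVesselRadial, 0)
  expect_equal(lab2$radial$cell, "opposing")
  expect_equal(lab2$radial$number, "contributing")
  # all-zero strains are neutral everywhere
  lab0 <- labelMechanism(mk(0, 0, 0))
  expect_equal(lab0$radial$vessel, "stable")
  expect_equal(lab0$radial$cell, "neutral")
  expect_equal(lab0$axial$number, "neutral")
})

test_that("strain tables round-trip through CSV with residual column", {
  g <- genCellShapeTable(nCells = 5, noiseCv = 0, seed = 9)
  st <- strainAnalysis(g$vessels, g$cells)
  path <- tempfile(fileext = ".csv")
  df <- writeStrainTable(st, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2 * length(st))
  expect_true(all(abs(back$identity_residual) < 1e-12))
})
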