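# Generators: determinism, ground truth attached, noiseless output matches
# the closed-form definition.

test_that("wall profile generator is deterministic and carries its truth", {
  g <- genWallProfile(wallCenters = c(2, 12), noiseSd = 0)
  expect_equal(g$trueDiameter, 10)
  g1 <- genWallProfile(wallCenters = c(3, 9), noiseSd = 0.05, seed = 7)
  g2 <- genWallProfile(wallCenters = c(3, 9), noiseSd = 0.05, seed = 7)
  expect_identical(intensities(g1$profile), intensities(g2$profile))
  g3 <- genWallProfile(wallCenters = c(3, 9), noiseSd = 0.05, seed = 8)
  expect_false(identical(intensities(g1$profile), intensities(g3$profile)))
})

test_that("noiseless gaussian walls peak at the specified centres", {
  g <- genWallProfile(wallCenters = c(3, 9), wallShape = "gaussian",
                      wallHalfwidth = 0.3, noiseSd = 0.02, seed = 7)
  x <- positions(g$noiseless); y <- intensities(g$noiseless)
  # independent check: evaluate the analytic profile on the same grid
  analytic <- 0.1 + exp(-(x - 3)^2 / (2 * 0.3^2)) +
    exp(-(x - 9)^2 / (2 * 0.3^2))
  expect_equal(y, analytic, tolerance = 1e-12)
  left <- x < 6
  expect_equal(x[left][which.max(y[left])], 3, tolerance = 0.1)
  expect_equal(x[!left][which.max(y[!left])], 9, tolerance = 0.1)
})

test_that("overlapping walls are rejected", {
  expect_error(genWallProfile(wallCenters = c(5, 5.4), wallHalfwidth = 0.5),
               "unresolvable")
  expect_error(genWallProfile(wallCenters = c(5, 5)), "distinct")
})

test_that("cell shape tables: zero noise reproduces truth exactly", {
  g <- genCellShapeTable(nCells = 4, trueArea = c(100, 80),
                         trueAspect = c(4, 4), trueDiameter = c(10, 8),
                         trueLength = c(50, 60),
                         timepoints = c("t1", "t2"), noiseCv = 0, seed = 1)
  expect_true(all(g$cells$area_um2[g$cells$timepoint == "t1"] == 100))
  expect_true(all(g$cells$aspect_ratio == 4))
  # closed-form truth: cell-area strain (80-100)/100 = -0.2 means radial
  # cell strain on width sqrt(a/r): sqrt(80/4)/sqrt(100/4) - 1
  st <- g$truth$strains[["t1->t2"]]
  expect_equal(st@epsCellRadial, sqrt(20) / sqrt(25) - 1, tolerance = 1e-12)
  expect_equal(st@epsVesselRadial, -0.2, tolerance = 1e-12)
})

test_that("noisy sample means converge to truth within standard error", {
  g <- genCellShapeTable(nCells = 200, trueArea = 100, trueAspect = 3,
                         timepoints = "t1", noiseCv = 0.1, seed = 3)
  se <- g$truth$seMeanArea[1]
  expect_lt(abs(mean(g$cells$area_um2) - 100), 3 * se)
  # derived width/length columns satisfy the exact shape identities
  expect_equal(g$cells$width_um * g$cells$length_um, g$cells$area_um2,
               tolerance = 1e-12)
})

test_that("kymograph generator: gap grows linearly and edges sit at truth", {
  g0 <- genKymograph(trueVelocity = 0, nFrames = 20, noiseSd = 0)
  expect_equal(diff(range(g0$trueGap, na.rm = TRUE)), 0)
  g <- genKymograph(trueVelocity = 0.4, frameInterval = 0.25, noiseSd = 0)
  gaps <- g$trueGap[!is.na(g$trueGap)]
  expect_equal(unique(round(diff(gaps), 12)), 0.1)  # 0.4 um/s * 0.25 s
  # half-max edge positions of the noiseless image within 1 px of truth
  gb <- genKymograph(trueVelocity = 0.4, edgeBlur = 0.2, noiseSd = 0.05,
                     seed = 11)
  k <- 30
  colv <- gb$noiseless[, k]
  x <- (seq_along(colv) - 0.5) * 0.1
  centre <- 6
  trueL <- centre - gb$trueGap[k] / 2
  xf <- seq(min(x), max(x), by = 0.001)  # dense-grid crossing search
  yf <- approx(x, colv, xf)$y
  iL <- which(diff(yf < 0.5) != 0)
  expect_lt(min(abs(xf[iL] - trueL)), 0.1)
  expect_error(genKymograph(trueVelocity = 2, nFrames = 100, fieldWidth = 8),
               "out of field")
})

test_that("lagged series: construction honours the prescribed shift", {
  g <- genLaggedSeries(trueLag = 2.5, frameInterval = 0.5, noiseSd = 0,
                       correlationSign = "positive", seed = 2)
  a <- traceValues(g$a); b <- traceValues(g$b)
  expect_equal(b[6:length(b)], a[1:(length(a) - 5)], tolerance = 1e-12)
  gn <- genLaggedSeries(trueLag = 2.5, frameInterval = 0.5, noiseSd = 0,
                        correlationSign = "negative", seed = 2)
  expect_equal(traceValues(gn$b)[6:200], -a[1:195], tolerance = 1e-12)
  # zero lag: arg-max of the cross-correlation sits at 0
  g0 <- genLaggedSeries(trueLag = 0, noiseSd = 0,
                        correlationSign = "positive", seed = 5)
  expect_equal(crosscorrLag(g0$a, g0$b, maxLag = 10)$lag, 0)
})

test_that("oriented textures have the constructed gradient structure", {
  texL <- genOrientedTexture("L", seed = 1)
  # longitudinal stripes vary across rows only: gradient energy along y
  gy <- diff(texL$image)
  gx <- t(diff(t(texL$image)))
  expect_gt(sum(gy^2), 100 * sum(gx^2))
  # rotating a C texture by 90 degrees turns it into an L classification
  texC <- genOrientedTexture("C", seed = 1)
  rot <- t(texC$image[nrow(texC$image):1, ])
  expect_equal(orientationLabel(classifyOrientation(rot)), "L")
})
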