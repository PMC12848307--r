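# Diameter estimation, polyline length, cell shape identities, effective
# cell numbers.

test_that("diameter from symmetric triangular walls equals centre distance", {
  g <- genWallProfile(wallCenters = c(2, 12), noiseSd = 0)
  est <- diameterFromProfile(g$profile)
  expect_equal(diameter(est), 10, tolerance = 1e-9)
  # mirrored profile gives the identical diameter
  p <- g$profile
  mir <- intensityProfile(rev(max(positions(p)) - positions(p)),
                          rev(intensities(p)))
  expect_equal(diameter(diameterFromProfile(mir)), 10, tolerance = 1e-9)
})

test_that("diameter is invariant to intensity rescaling and offset", {
  g <- genWallProfile(wallCenters = c(3, 9), wallShape = "gaussian",
                      wallHalfwidth = 0.3, noiseSd = 0.01, seed = 2)
  p <- g$profile
  d1 <- diameter(diameterFromProfile(p))
  p2 <- intensityProfile(positions(p), 7.3 * intensities(p) + 11)
  expect_equal(diameter(diameterFromProfile(p2)), d1, tolerance = 1e-9)
})

test_that("noiseless recovery is within half a pixel; noisy within spec", {
  for (shape in c("triangle", "gaussian")) {
    g <- genWallProfile(wallCenters = c(2.53, 8.91), wallShape = shape,
                        wallHalfwidth = 0.4, noiseSd = 0)
    expect_lt(abs(diameter(diameterFromProfile(g$profile)) - g$trueDiameter),
              0.5 * 0.1)
  }
  g <- genWallProfile(wallCenters = c(3, 9), wallShape = "gaussian",
                      wallHalfwidth = 0.3, noiseSd = 0.02, seed = 7)
  expect_lt(abs(diameter(diameterFromProfile(g$profile)) - 6), 0.1)
})

test_that("profiles without two walls are rejected", {
  x <- seq(0, 10, 0.1)
  single <- intensityProfile(x, 0.1 + exp(-(x - 5)^2 / 0.5))
  expect_error(diameterFromProfile(single), "walls not found")
  flat <- intensityProfile(x, rep(0.1, length(x)))
  expect_error(diameterFromProfile(flat), "walls not found")
})

test_that("meanDiameter averages and flags insufficient replicates", {
  ests <- lapply(c(9, 10, 11), function(d)
    new("DiameterEstimate", diameter = d, wallPositions = c(0, d),
        nProfilesAveraged = 1L))
  m <- meanDiameter(ests)
  expect_equal(diameter(m), 10)
  expect_equal(m@nProfilesAveraged, 3L)
  expect_warning(meanDiameter(c(10, 10)), "insufficient")
  # five noisy synthetic measurements of a 6-um vessel
  d5 <- vapply(1:5, function(s) {
    g <- genWallProfile(wallCenters = c(3, 9), wallShape = "gaussian",
                        wallHalfwidth = 0.3, noiseSd = 0.02, seed = s)
    diameter(diameterFromProfile(g$profile))
  }, numeric(1))
  expect_lt(abs(diameter(meanDiameter(d5)) - 6), 0.05)
})

test_that("polyline length matches the brute-force oracle and is rigid", {
  expect_equal(polylineLength(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(polylineLength(rbind(c(0, 0), c(1, 0), c(2, 0))), 2)
  set.seed(10)
  pts <- matrix(rnorm(20), ncol = 2)
  # independent loop summation
  oracle <- 0
  for (i in 2:nrow(pts))
    oracle <- oracle + sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
  expect_equal(polylineLength(pts), oracle, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(polylineLength(pts %*% R), oracle, tolerance = 1e-12)
  expect_error(polylineLength(rbind(c(0, 0))), "degenerate")
})

test_that("cell width/length satisfy their defining identities", {
  wl <- cellWidthLength(100, 4)
  expect_equal(wl$w, 5)
  expect_equal(wl$l, 20)
  wl1 <- cellWidthLength(57.3, 1)
  expect_equal(wl1$w, wl1$l)
  wl2 <- cellWidthLength(60.84, 2.5)
  expect_equal(wl2$w * wl2$l, 60.84, tolerance = 1e-12)
  expect_equal(wl2$l / wl2$w, 2.5, tolerance = 1e-12)
  expect_error(cellWidthLength(-1, 2), "invalid shape")
  expect_error(cellWidthLength(10, 0), "invalid shape")
})

test_that("effective cell numbers follow the definitions exactly", {
  n <- effectiveCellNumbers(D = 10, L = 100, w = 5, l = 20)
  expect_equal(n$radial, 2 * pi)
  expect_equal(n$axial, 5)
  # one cell wrapping the circumference
  n1 <- effectiveCellNumbers(D = 3, L = 10, w = pi * 3, l = 10)
  expect_equal(n1$radial, 1)
  # reconstruction identities hold by construction
  expect_equal(n$radial * 5, pi * 10, tolerance = 1e-12)
  expect_error(effectiveCellNumbers(-1, 1, 1, 1), "invalid geometry")
})

test_that("profile extraction from an image matches direct sampling", {
  img <- outer(seq_len(40), seq_len(60), function(r, c) c / 10)
  pr <- profileFromImage(img, row = 20, col = 5, angle = 0, length = 4,
                         pixelSize = 0.1)
  # along a row, intensity is linear in column index
  expect_equal(intensities(pr), (5 + positions(pr) / 0.1) / 10,
               tolerance = 1e-9)
  expect_error(profileFromImage(img, 20, 55, 0, 4, 0.1), "leaves the image")
})
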