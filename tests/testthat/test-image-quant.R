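# Trace normalisation, junction/cortex ratios, kymograph velocimetry,
# cross-correlation lag and the orientation classifier.

test_that("background subtraction shifts values", {
  tr <- intensityTrace(1:2, c(5, 6))
  expect_equal(traceValues(backgroundSubtract(tr, 5)), c(0, 1))
  expect_equal(traceValues(backgroundSubtract(tr, 0)), c(5, 6))
})

test_that("log/max-min normalisation maps to [0,1] with both bounds", {
  tr <- intensityTrace(1:3, c(1, 10, 100))
  expect_equal(traceValues(logMinmaxNormalize(tr)), c(0, 0.5, 1))
  tr2 <- intensityTrace(1:3, c(1, 2, 3))
  expect_equal(traceValues(logMinmaxNormalize(tr2)),
               c(0, log10(2) / log10(3), 1), tolerance = 1e-12)
  # affine gain above the floor does not change the output
  tr3 <- intensityTrace(1:3, 50 * c(1, 2, 3))
  expect_equal(traceValues(logMinmaxNormalize(tr3)),
               traceValues(logMinmaxNormalize(tr2)), tolerance = 1e-12)
  set.seed(1)
  v <- exp(rnorm(40, 2, 1))
  out <- traceValues(logMinmaxNormalize(intensityTrace(seq_along(v), v)))
  expect_equal(range(out), c(0, 1))
  expect_error(logMinmaxNormalize(intensityTrace(1:3, rep(2, 3))),
               "zero dynamic range")
  expect_warning(logMinmaxNormalize(intensityTrace(1:3, c(-1, 1, 10))),
                 "clipped")
})

test_that("junction/cortex ratio matches hand arithmetic and gain-invariance", {
  expect_equal(junctionCortexRatio(rep(20, 6), rep(2, 10), c(0, 0))$log10Ratio,
               1)
  expect_equal(junctionCortexRatio(rep(5, 6), rep(5, 10), c(0, 0))$log10Ratio,
               0)
  expect_equal(junctionCortexRatio(rep(21, 6), rep(3, 10), c(1, 1))$log10Ratio,
               log10(20 / 2))
  # common multiplicative gain on all ROIs leaves the ratio unchanged
  r1 <- junctionCortexRatio(rep(21, 6), rep(3, 10), c(1, 1))$log10Ratio
  r2 <- junctionCortexRatio(rep(21, 6) * 4, rep(3, 10) * 4,
                            c(1, 1) * 4)$log10Ratio
  expect_equal(r2, r1, tolerance = 1e-12)
  expect_error(junctionCortexRatio(rep(1, 6), rep(3, 10), c(2, 2)),
               "below background")
  expect_warning(junctionCortexRatio(rep(21, 4), rep(3, 10), c(1, 1)),
                 "ROI counts")
})

test_that("gap tracing recovers the true gap and ignores pre-ablation frames", {
  g <- genKymograph(trueVelocity = 0.4, noiseSd = 0)
  gap <- traceGapEdges(g$kymograph)
  expect_true(all(is.na(gap[1:4])))                 # before ablation frame 5
  ok <- !is.na(gap)
  expect_true(any(ok))
  expect_lt(max(abs(gap[ok] - g$trueGap[ok])), 0.5 * 0.1)
  # fractional threshold makes the trace invariant to intensity rescaling
  k2 <- kymograph(3 * g$kymograph@matrix + 2, 0.1, 0.25, 5L)
  expect_equal(traceGapEdges(k2), gap, tolerance = 1e-9)
})

test_that("recoil velocity: displacement/time equals the constructed rate", {
  gap <- c(rep(NA, 4), 1 + 0.1 * (0:45))            # +0.1 um per 0.25 s frame
  tt <- (0:49) * 0.25
  rv <- recoilVelocity(gap, tt, window = 10)
  expect_equal(rv$velocity, 0.4, tolerance = 1e-9)
  expect_equal(rv$slope, 0.4, tolerance = 1e-9)
  # constant gap gives zero velocity
  expect_equal(recoilVelocity(c(NA, rep(2, 20)), (0:20) * 0.5)$velocity, 0)
  expect_error(recoilVelocity(rep(NA_real_, 10), 1:10), "window too short")
})

test_that("noisy synthetic recoil matches truth and the least-squares oracle", {
  g <- genKymograph(trueVelocity = 0.5, noiseSd = 0.04, seed = 11)
  gap <- traceGapEdges(g$kymograph)
  tt <- (seq_along(gap) - 1) * g$kymograph@frameInterval
  rv <- recoilVelocity(gap, tt, window = 10)
  expect_lt(abs(rv$velocity - 0.5), 0.05)
  expect_lt(abs(rv$velocity - rv$slope), 0.02)
  m <- meanRecoil(c(0.5, 0.4, 0.6))
  expect_equal(m$meanVelocity, 0.5)
})

test_that("cross-correlation lag is exact at integer-frame shifts", {
  g <- genLaggedSeries(trueLag = 2.5, frameInterval = 0.5, noiseSd = 0,
                       correlationSign = "positive", seed = 3)
  res <- crosscorrLag(g$a, g$b, maxLag = 10, refine = FALSE)
  expect_equal(res$lag, 2.5, tolerance = 1e-9)
  expect_gt(res$correlation, 0.999)
  # parabolic refinement stays within a quarter frame of the exact lag
  resR <- crosscorrLag(g$a, g$b, maxLag = 10)
  expect_lt(abs(resR$lag - 2.5), 0.125)
  # anti-correlated pair at zero shift
  a <- intensityTrace(1:100, sin((1:100) / 5))
  b <- intensityTrace(1:100, -sin((1:100) / 5))
  res2 <- crosscorrLag(a, b, maxLag = 20)
  expect_equal(res2$lag, 0)
  expect_equal(res2$correlation, -1, tolerance = 1e-9)
  expect_error(crosscorrLag(a, b, maxLag = 60), "insufficient")
})

test_that("noisy negative-sign lag is recovered within one frame", {
  g <- genLaggedSeries(trueLag = 2.5, frameInterval = 0.5, noiseSd = 0.1,
                       correlationSign = "negative", seed = 4)
  res <- crosscorrLag(g$a, g$b, maxLag = 10, which = "min")
  expect_lt(abs(res$lag - 2.5), 0.5)
  expect_lt(res$correlation, 0)
  # brute-force scan oracle agrees on the integer lag
  av <- traceValues(g$a); bv <- traceValues(g$b); n <- length(av)
  rs <- vapply(-20:20, function(k) {
    ia <- seq_len(n - abs(k))
    if (k >= 0) cor(av[ia], bv[ia + k]) else cor(av[ia + abs(k)], bv[ia])
  }, numeric(1))
  expect_equal(round(res$lag / 0.5), (-20:20)[which.min(rs)])
})

test_that("orientation classifier separates the three texture classes", {
  expect_equal(orientationLabel(classifyOrientation(
    genOrientedTexture("L", seed = 1)$image)), "L")
  expect_equal(orientationLabel(classifyOrientation(
    genOrientedTexture("C", seed = 1)$image)), "C")
  callM <- classifyOrientation(genOrientedTexture("M", seed = 2)$image)
  expect_equal(orientationLabel(callM), "M")
  expect_lt(coherence(callM), 0.2)
  expect_error(classifyOrientation(matrix(1, 10, 10)), "no texture")
})

test_that("classifier panel accuracy is at least 90 percent", {
  labels <- rep(c("C", "M", "L"), each = 20)
  calls <- vapply(seq_along(labels), function(i) {
    tex <- genOrientedTexture(labels[i], angleJitterSd = 8, noiseSd = 0.3,
                              seed = 100 + i)
    orientationLabel(classifyOrientation(tex$image))
  }, character(1))
  expect_gte(mean(calls == labels), 0.9)
})

test_that("mesh texture coherence agrees with an FFT anisotropy oracle", {
  tex <- genOrientedTexture("M", seed = 2)$image
  # oracle: energy anisotropy of the Fourier spectrum
  F2 <- Mod(stats::fft(tex))^2
  n <- nrow(tex)
  fr <- c(0:(n / 2), -((n / 2 - 1):1)) # frequency index per row/col
  fx <- matrix(fr, n, n, byrow = TRUE); fy <- matrix(fr, n, n)
  w <- F2; w[1, 1] <- 0
  jxx <- sum(w * fx^2); jyy <- sum(w * fy^2); jxy <- sum(w * fx * fy)
  ori <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy)
  expect_lt(ori, 0.2)
  expect_lt(coherence(classifyOrientation(tex)), 0.2)
  # and a striped texture is strongly anisotropic under both measures
  texL <- genOrientedTexture("L", seed = 2)$image
  F2L <- Mod(stats::fft(texL))^2; F2L[1, 1] <- 0
  jxxL <- sum(F2L * fx^2); jyyL <- sum(F2L * fy^2); jxyL <- sum(F2L * fx * fy)
  expect_gt(sqrt((jxxL - jyyL)^2 + 4 * jxyL^2) / (jxxL + jyyL), 0.8)
  expect_gt(coherence(classifyOrientation(texL)), 0.8)
})

test_that("front/back views combine into ordered categories", {
  expect_equal(combineViews("C", "C"), "C")
  expect_equal(combineViews("M", "C"), "C-M")
  expect_equal(combineViews("C", "M"), "C-M")
  expect_equal(combineViews("L", "M"), "M-L")
  expect_equal(combineViews("L", "C"), "C-L")
})
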