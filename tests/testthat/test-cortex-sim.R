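# Mechanics of the cortex model: parameter validity, initial conditions,
# virial-stress oracle equivalence, alignment sum rule, conservation laws,
# relaxation, and reproducibility.

quietParams <- function(...) {
  cortexParams("reduced_test", ...)
}

test_that("presets are self-consistent and obey the stability bound", {
  p <- cortexParams("paper_like")
  expect_equal(unname(p@domain[c("Lx", "Ly")]), c(8, 30))
  expect_equal(unname(p@filament[["anchoredLength"]]), 2)
  expect_lte(p@counts[["nAnchored"]], 0.01 * p@counts[["nFilaments"]])
  r <- cortexParams("reduced_test")
  # identical physics constants, smaller counts
  expect_identical(p@filament, r@filament)
  expect_identical(p@motor, r@motor)
  expect_identical(p@numerics, r@numerics)
  expect_lt(r@counts[["nFilaments"]], p@counts[["nFilaments"]])
  # dt below the stability bound for the stiffest spring
  kMax <- max(p@filament[["stretchStiffness"]], p@motor[["linkStiffness"]],
              p@crosslinker[["stiffness"]],
              p@numerics[["confinementStiffness"]])
  expect_lt(p@numerics[["dt"]], p@numerics[["drag"]] / (4 * kMax))
  # violating the bound is rejected
  expect_error(cortexParams("reduced_test", "numerics.dt" = 0.1),
               "stability bound")
  expect_error(cortexParams("reduced_test", "motor.bogus" = 1), "unknown")
})

test_that("initialisation honours anchoring mode, counts and determinism", {
  p0 <- quietParams(anchoring = "none")
  s0 <- initCortex(p0, seed = 1)
  expect_equal(sum(vapply(s0@filaments, function(f) f$anchored, TRUE)), 0)
  p <- cortexParams("paper_like", anchoring = "longitudinal_membrane")
  s <- initCortex(p, seed = 1)
  anch <- Filter(function(f) f$anchored, s@filaments)
  expect_equal(length(anch), 4)          # 1% of 400
  sides <- vapply(anch, function(f) f$anchor[1], 0)
  expect_equal(sum(sides == 0), 2)       # two per side
  expect_equal(sum(sides == 8), 2)
  expect_equal(length(s@filaments), 400)
  sA <- initCortex(p, seed = 7)
  sB <- initCortex(p, seed = 7)
  expect_identical(sA@filaments, sB@filaments)
  sC <- initCortex(p, seed = 8)
  expect_false(identical(sA@filaments, sC@filaments))
})

test_that("virial stress: one-pair closed form and 90-degree rotation", {
  led <- cbind(rx = 1, ry = 0, fx = 1, fy = 0, mx = 0.5, my = 0.5)
  s <- computeStress(led, area = 1)
  expect_equal(unname(s), c(1, 0, 0))
  rot <- cbind(rx = 0, ry = 1, fx = 0, fy = 1, mx = 0.5, my = 0.5)
  s2 <- computeStress(rot, area = 1)
  expect_equal(unname(s2), c(0, 1, 0))
  expect_error(computeStress(led, region = c(5, 6, 5, 6), area = 1),
               "no pairs")
})

test_that("stress equals a brute-force pairwise sum on random spring nets", {
  set.seed(42)
  for (rep in 1:100) {
    nb <- sample(4:20, 1)
    beads <- cbind(runif(nb, 0, 4), runif(nb, 0, 4))
    ns <- sample(3:12, 1)
    springs <- cbind(sample(nb, ns, TRUE), sample(nb, ns, TRUE),
                     runif(ns, 10, 100), runif(ns, 0.1, 1))
    springs <- springs[springs[, 1] != springs[, 2], , drop = FALSE]
    if (nrow(springs) == 0) next
    led <- t(apply(springs, 1, function(sp) {
      i <- sp[1]; j <- sp[2]
      r <- beads[i, ] - beads[j, ]
      d <- sqrt(sum(r^2))
      f <- sp[3] * (d - sp[4]) * r / d       # force on j, toward i if taut
      c(rx = r[1], ry = r[2], fx = f[1], fy = f[2],
        mx = mean(beads[c(i, j), 1]), my = mean(beads[c(i, j), 2]))
    }))
    colnames(led) <- c("rx", "ry", "fx", "fy", "mx", "my")
    got <- computeStress(led, area = 16)
    # independent O(n^2) oracle: loop over all bead pairs, find springs
    oxx <- oyy <- oxy <- 0
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      if (i <= j) next
      for (k in seq_len(nrow(springs))) {
        if (!((springs[k, 1] == i && springs[k, 2] == j) ||
              (springs[k, 1] == j && springs[k, 2] == i))) next
        a <- springs[k, 1]; b <- springs[k, 2]
        r <- beads[a, ] - beads[b, ]
        d <- sqrt(sum(r^2))
        f <- springs[k, 3] * (d - springs[k, 4]) * r / d
        oxx <- oxx + f[1] * r[1]; oyy <- oyy + f[2] * r[2]
        oxy <- oxy + 0.5 * (f[1] * r[2] + f[2] * r[1])
      }
    }
    expect_equal(unname(got), c(oxx, oyy, oxy) / 16, tolerance = 1e-10)
  }
})

test_that("region additivity: partition stresses area-sum to the whole", {
  p <- quietParams()
  st <- stepCortex(initCortex(p, seed = 5), 200, seed = 5)
  led <- pairForces(st)
  Lx <- 8; Ly <- 30
  whole <- computeStress(led, region = c(-10, 20, 0, Ly), area = Lx * Ly)
  cuts <- c(0, 10, 20, Ly)
  parts <- lapply(1:3, function(k)
    computeStress(led, region = c(-10, 20, cuts[k], cuts[k + 1]),
                  area = Lx * (cuts[k + 1] - cuts[k])))
  areas <- Lx * diff(cuts)
  recon <- Reduce(`+`, Map(function(s, a) s * a, parts, areas)) / (Lx * Ly)
  expect_equal(recon, whole, tolerance = 1e-9)
})

test_that("stress from the simulation ledger matches an R-side recompute", {
  # dual route: C++ ledger summation vs direct R arithmetic on the ledger
  p <- quietParams()
  st <- stepCortex(initCortex(p, seed = 2), 100, seed = 3)
  led <- pairForces(st)
  s <- computeStress(st)
  expect_equal(s[["sxx"]], sum(led[, "fx"] * led[, "rx"]) / (8 * 30),
               tolerance = 1e-12)
})

test_that("alignment sum rule holds exactly; extremes behave", {
  p <- quietParams(anchoring = "none")
  st <- initCortex(p, seed = 9)
  al <- computeAlignment(st)
  expect_identical(al$Nx2 + al$Ny2, al$S + 0)      # exact by construction
  # all segments along x
  stx <- st
  stx@filaments <- lapply(stx@filaments, function(f) {
    n <- nrow(f$beads)
    f$beads <- cbind(2 + (seq_len(n) - 1) * 0.5, f$beads[1, 2])
    f
  })
  alx <- computeAlignment(stx)
  expect_equal(alx$Nx2, alx$S)
  sty <- st
  sty@filaments <- lapply(sty@filaments, function(f) {
    n <- nrow(f$beads)
    f$beads <- cbind(f$beads[1, 1], 5 + (seq_len(n) - 1) * 0.5)
    f
  })
  expect_equal(computeAlignment(sty)$Nx2, 0)
})

test_that("isotropic orientations give Nx2/S = 0.5 (Monte Carlo)", {
  # E[cos^2 theta] = 1/2 in 2D; S = 1e4 segments
  set.seed(123)
  th <- runif(1e4, 0, 2 * pi)
  nx2 <- sum(cos(th)^2)
  expect_lt(abs(nx2 / 1e4 - 0.5), 0.02)
  # the freshly initialised network is near-isotropic, up to the modest
  # longitudinal bias that confinement imposes on filaments longer than
  # their distance to a wall
  p <- cortexParams("paper_like", anchoring = "none")
  st <- initCortex(p, seed = 3)
  al <- computeAlignment(st)
  expect_lt(abs(al$Nx2 / al$S - 0.5), 0.15)
})

test_that("relaxed isolated filament is a fixed point; energy decreases", {
  p <- quietParams(anchoring = "none", "counts.nFilaments" = 1,
                   "counts.nMotors" = 0, "counts.nCrosslinkers" = 0,
                   "numerics.thermalNoise" = 0, "kinetics.turnoverRate" = 0,
                   "kinetics.polymerRate" = 0, "kinetics.depolymerRate" = 0)
  st <- initCortex(p, seed = 4)
  st2 <- stepCortex(st, 50, seed = 1)
  expect_equal(unname(st2@filaments[[1]]$beads),
               unname(st@filaments[[1]]$beads), tolerance = 1e-12)
  # stretched spring: elastic energy strictly decreases step by step
  stS <- st
  stS@filaments[[1]]$beads[1, 1] <- stS@filaments[[1]]$beads[1, 1] + 0.2
  sl <- vesselmech:::.stateForCpp(stS)
  pl <- vesselmech:::.paramsForCpp(p)
  e <- vesselmech:::cpp_energy(sl, pl)
  cur <- stS
  for (k in 1:5) {
    cur <- stepCortex(cur, 20, seed = k)
    e2 <- vesselmech:::cpp_energy(vesselmech:::.stateForCpp(cur), pl)
    expect_lt(e2, e)
    e <- e2
  }
})

test_that("internal forces sum to zero without anchors or membranes", {
  p <- quietParams(anchoring = "none", "numerics.thermalNoise" = 0)
  st <- stepCortex(initCortex(p, seed = 6), 100, seed = 6)
  ff <- vesselmech:::cpp_bead_forces(vesselmech:::.stateForCpp(st),
                                     vesselmech:::.paramsForCpp(p))
  tot <- Reduce(`+`, lapply(ff$filaments, colSums))
  expect_lt(max(abs(tot)), 1e-9)
})

test_that("bead forces equal the numerical energy gradient", {
  p <- quietParams(anchoring = "none", "counts.nFilaments" = 3,
                   "counts.nMotors" = 2, "counts.nCrosslinkers" = 2,
                   "numerics.thermalNoise" = 0)
  st <- initCortex(p, seed = 7)
  set.seed(1)
  for (i in 1:3)
    st@filaments[[i]]$beads <- st@filaments[[i]]$beads +
      matrix(rnorm(length(st@filaments[[i]]$beads), 0, 0.05), ncol = 2)
  st@motors[1, ] <- c(1, 0.3, 2, 0.6)    # bind one motor across filaments
  pl <- vesselmech:::.paramsForCpp(p)
  ff <- vesselmech:::cpp_bead_forces(vesselmech:::.stateForCpp(st),
                                     pl)$filaments
  h <- 1e-6
  for (fi in 1:3) for (b in c(1, nrow(st@filaments[[fi]]$beads))) for (d in 1:2) {
    sp <- st; sp@filaments[[fi]]$beads[b, d] <-
      sp@filaments[[fi]]$beads[b, d] + h
    sm <- st; sm@filaments[[fi]]$beads[b, d] <-
      sm@filaments[[fi]]$beads[b, d] - h
    num <- -(vesselmech:::cpp_energy(vesselmech:::.stateForCpp(sp), pl) -
               vesselmech:::cpp_energy(vesselmech:::.stateForCpp(sm), pl)) /
      (2 * h)
    expect_equal(ff[[fi]][b, d], num, tolerance = 1e-4)
  }
})

test_that("filament count is conserved and runs are bit-reproducible", {
  p <- quietParams()
  trA <- runCortex(p, duration = 20, recordEvery = 2, seed = 11)
  trB <- runCortex(p, duration = 20, recordEvery = 2, seed = 11)
  expect_identical(trA@stress, trB@stress)
  expect_identical(trA@finalState@filaments, trB@finalState@filaments)
  expect_equal(length(trA@finalState@filaments),
               as.integer(p@counts[["nFilaments"]]))
  trC <- runCortex(p, duration = 20, recordEvery = 2, seed = 12)
  expect_false(identical(trA@stress$sxx, trC@stress$sxx))
})

test_that("vessel width: flat membranes, symmetric bumps, trapezoid oracle", {
  p <- quietParams(boundaryMode = "deformable_membrane")
  st <- initCortex(p, seed = 1)
  expect_equal(vesselWidth(st), 8)
  # symmetric inward bumps of depth 1 um spanning the region give width 6
  stB <- st
  stB@membranes$left <- rep(1, length(stB@membranes$left))
  stB@membranes$right <- rep(7, length(stB@membranes$right))
  expect_equal(vesselWidth(stB), 6)
  # smooth random perturbation: equals numerical integration oracle
  stR <- st
  y <- stR@membranes$y
  stR@membranes$left <- 0.5 * sin(2 * pi * y / 30)^2
  stR@membranes$right <- 8 - 0.3 * cos(2 * pi * y / 30)^2
  got <- vesselWidth(stR, region = c(0, 8, 10, 20))
  yy <- seq(10, 20, length.out = 2001)
  gap <- approx(y, stR@membranes$right, yy)$y -
    approx(y, stR@membranes$left, yy)$y
  oracle <- sum((gap[-1] + gap[-length(gap)]) / 2) / (length(gap) - 1)
  expect_equal(got, oracle, tolerance = 1e-3)
  # crossing membranes are an error
  stX <- st
  stX@membranes$right <- rep(-1, length(stX@membranes$right))
  expect_error(vesselWidth(stX), "membrane collision")
  # fixed walls report the domain width
  expect_equal(vesselWidth(initCortex(quietParams(), seed = 1)), 8)
})

test_that("run artifacts are written with provenance", {
  p <- quietParams()
  tr <- runCortex(p, duration = 10, recordEvery = 2, seed = 3)
  dir <- file.path(tempdir(), "runtest")
  writeRun(tr, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "particles.csv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 3)
  expect_equal(prov$domain$Lx, 8)
})
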