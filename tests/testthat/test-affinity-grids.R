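test_that("ionic strength follows I = 1/2 sum c z^2", {
  nacl <- ionicSolvent(data.frame(concentration = c(0.1, 0.1),
                                  valence = c(1, -1)))
  expect_equal(ionicStrength(nacl), 0.1)
  # 0.1 M NaCl + 0.01 M MgCl2: 1/2 (0.1 + 0.1 + 0.01*4 + 0.02) = 0.13
  expect_equal(ionicStrength(referenceSolvent()), 0.13)
  water <- ionicSolvent(data.frame(concentration = numeric(),
                                   valence = integer()))
  expect_equal(ionicStrength(water), 0)
  expect_error(ionicSolvent(data.frame(concentration = 0.1, valence = 1)),
               "electroneutral")
})

test_that("Debye screening length matches the closed form and scaling law", {
  nacl298 <- ionicSolvent(data.frame(concentration = c(0.1, 0.1),
                                     valence = c(1, -1)), temperature = 298)
  kappa <- inverseDebyeLength(nacl298)
  # textbook value: about 0.96 nm at 0.1 M monovalent salt
  expect_equal(1 / kappa, 9.6, tolerance = 0.02)
  water <- ionicSolvent(data.frame(concentration = numeric(),
                                   valence = integer()))
  expect_equal(inverseDebyeLength(water), 0)
  double <- ionicSolvent(data.frame(concentration = c(0.2, 0.2),
                                    valence = c(1, -1)), temperature = 298)
  expect_equal(inverseDebyeLength(double), sqrt(2) * kappa,
               tolerance = 1e-12)
})

test_that("single-charge potential matches the Coulomb closed form", {
  p <- singleAtomProtein(charge = 1, radius = 1.5)
  geom <- list(origin = c(10, 0, 0), spacing = c(1, 1, 1), shape = c(1, 1, 1))
  water <- ionicSolvent(data.frame(concentration = numeric(),
                                   valence = integer()), epsWater = 79)
  g <- dhPotentialGrid(p, geom, water)
  expect_equal(as.vector(gridValues(g)), 1389.35 / (79 * 10),
               tolerance = 1e-4)
})

test_that("DH potential is a superposition and is damped by screening", {
  geom <- list(origin = c(-6, -6, -6), spacing = c(2, 2, 2),
               shape = c(7, 7, 7))
  water <- ionicSolvent(data.frame(concentration = numeric(),
                                   valence = integer()))
  p1 <- singleAtomProtein(3, 0, 0, charge = 1)
  p2 <- singleAtomProtein(-3, 1, 0, charge = -0.5)
  both <- combineStructures(p1, p2)
  g1 <- dhPotentialGrid(p1, geom, water)
  g2 <- dhPotentialGrid(p2, geom, water)
  gb <- dhPotentialGrid(both, geom, water)
  expect_equal(gridValues(gb), gridValues(g1) + gridValues(g2),
               tolerance = 1e-12)

  # screening damps the potential pointwise (same-sign sources, so no
  # cancellation effects between differently screened terms)
  samesign <- combineStructures(singleAtomProtein(3, 0, 0, charge = 1),
                                singleAtomProtein(-3, 1, 0, charge = 0.5))
  gu <- dhPotentialGrid(samesign, geom, water)
  gs <- dhPotentialGrid(samesign, geom, referenceSolvent())
  expect_true(all(abs(gridValues(gs)) <= abs(gridValues(gu)) + 1e-12))
})

test_that("near-atom nodes are clamped to the 0.5-A value", {
  p <- singleAtomProtein(0, 0, 0, charge = 1)
  geom <- list(origin = c(0, 0, 0), spacing = c(0.25, 1, 1),
               shape = c(4, 1, 1))
  water <- ionicSolvent(data.frame(concentration = numeric(),
                                   valence = integer()))
  g <- gridValues(dhPotentialGrid(p, geom, water))
  expect_equal(g[1, 1, 1], g[2, 1, 1])  # r = 0 and r = 0.25 both clamp to 0.5
  expect_gt(g[2, 1, 1], g[4, 1, 1])     # r = 0.75 is past the clamp
})

test_that("steric mask forbids nodes strictly inside padded vdW spheres", {
  p <- singleAtomProtein(0, 0, 0, radius = 2)
  geom <- list(origin = c(-4, -4, -4), spacing = c(1, 1, 1),
               shape = c(9, 9, 9))
  m <- stericMask(p, geom)
  # lattice points with squared distance < 4: 1 + 6 + 12 + 8 = 27
  expect_equal(sum(gridForbidden(m)), 27L)
  expect_true(gridForbidden(m)[5, 5, 5])
  # node exactly at the radius is allowed (strict inequality)
  expect_false(gridForbidden(m)[7, 5, 5])
  # padding grows the excluded ball
  m2 <- stericMask(p, geom, probePad = 1)
  expect_gt(sum(gridForbidden(m2)), 27)
})

test_that("rotation sets are deterministic, start at identity, and are uniform", {
  expect_identical(rotationSet(1, seed = 42)[[1]], diag(3))
  r1 <- rotationSet(150, seed = 42)
  r2 <- rotationSet(150, seed = 42)
  expect_identical(r1, r2)
  expect_error(rotationSet(0), ">= 1")
  # all are proper rotations
  for (R in r1[1:10]) {
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # Haar uniformity: the element-wise mean vanishes
  m <- Reduce(`+`, rotationSet(1e4, seed = 1)) / 1e4
  expect_lt(max(abs(m)), 0.05)
})

test_that("probe energy reduces to the potential for a point charge", {
  set.seed(1)
  pot <- valueGrid(array(rnorm(125), dim = c(5, 5, 5)), spacing = 2)
  probe <- Probe(c(0, 0, 0), charges = 1, label = "pt")
  for (R in rotationSet(5, seed = 2)) {
    expect_equal(probeEnergy(c(3, 3, 3), R, probe, pot),
                 gridValues(pot)[3, 3, 3], tolerance = 1e-12)
  }
  # negating all charges negates the energy
  probe2 <- Probe(rbind(c(1, 0, 0), c(-1, 0.5, 0)), charges = c(0.4, -0.8))
  probe2n <- Probe(rbind(c(1, 0, 0), c(-1, 0.5, 0)), charges = -c(0.4, -0.8))
  R <- rotationSet(3, seed = 9)[[2]]
  expect_equal(probeEnergy(c(3, 3, 3), R, probe2n, pot),
               -probeEnergy(c(3, 3, 3), R, probe2, pot), tolerance = 1e-12)
  # atoms out of the grid give +Inf
  expect_equal(probeEnergy(c(1, 1, 1), diag(3),
                           Probe(c(-5, 0, 0), 1), pot), Inf)
})

# independent literal re-implementation of trilinear interpolation
.oracleInterp <- function(grid, pt) {
  fr <- (pt - gridOrigin(grid)) / gridSpacing(grid)
  lo <- floor(fr + 1e-12)
  f <- fr - lo
  f[abs(f) < 1e-9] <- 0
  v <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- prod(ifelse(c(di, dj, dk) == 1, f, 1 - f))
    if (w == 0) next
    i <- lo + c(di, dj, dk) + 1
    sh <- gridShape(grid)
    if (any(i < 1) || any(i > sh)) return(Inf)
    if (gridForbidden(grid)[i[1], i[2], i[3]]) return(Inf)
    v <- v + w * gridValues(grid)[i[1], i[2], i[3]]
  }
  v
}

test_that("probe scan matches a brute-force per-node, per-rotation oracle", {
  set.seed(5)
  vals <- array(rnorm(125), dim = c(5, 5, 5))
  vals[2, 4, 3] <- 1e31  # one forbidden node
  pot <- valueGrid(vals, spacing = 2)
  probe <- Probe(rbind(c(1.1, 0, 0), c(-0.7, 0.9, 0.3)),
                 charges = c(0.5, -1.2))
  rots <- rotationSet(4, seed = 8)
  cfg <- scanConfig(nRotations = 4, mode = "min", seed = 8)
  scanned <- probeScan(pot, NULL, probe, cfg)
  kT <- thermalEnergy(300)
  cfgB <- scanConfig(nRotations = 4, mode = "boltzmann", seed = 8,
                     temperature = 300)
  scannedB <- probeScan(pot, NULL, probe, cfgB)
  off <- as.matrix(rbind(c(1.1, 0, 0), c(-0.7, 0.9, 0.3)))
  q <- c(0.5, -1.2)
  for (node in list(c(1, 1, 1), c(3, 3, 3), c(2, 3, 3), c(5, 5, 5),
                    c(3, 4, 3))) {
    ctr <- as.vector(nodeToCartesian(pot, node))
    eRot <- vapply(rots, function(R) {
      pts <- sweep(off %*% t(R), 2, ctr, "+")
      e <- 0
      for (a in 1:2) {
        phi <- .oracleInterp(pot, pts[a, ])
        if (!is.finite(phi)) return(Inf)
        e <- e + q[a] * phi
      }
      e
    }, numeric(1))
    expOracleMin <- min(eRot)
    got <- gridValues(scanned)[node[1], node[2], node[3]]
    if (is.finite(expOracleMin)) {
      expect_equal(got, expOracleMin, tolerance = 1e-9)
      fin <- is.finite(eRot)
      expB <- -kT * log(sum(exp(-eRot[fin] / kT)) / length(rots))
      gotB <- gridValues(scannedB)[node[1], node[2], node[3]]
      expect_equal(gotB, expB, tolerance = 1e-9)
      expect_gte(gotB + 1e-12, got)
    } else {
      expect_true(gridForbidden(scanned)[node[1], node[2], node[3]])
    }
  }
})

test_that("point-probe scans equal charge times potential in both modes", {
  set.seed(3)
  pot <- valueGrid(array(rnorm(64), dim = c(4, 4, 4)), spacing = 1.5)
  probe <- Probe(c(0, 0, 0), charges = 0.7)
  for (mode in c("min", "boltzmann")) {
    sc <- probeScan(pot, NULL, probe,
                    scanConfig(nRotations = 6, mode = mode, seed = 4))
    expect_equal(gridValues(sc), 0.7 * gridValues(pot), tolerance = 1e-9)
  }
})

test_that("scan results are invariant to rotation order and propagate masks", {
  set.seed(6)
  vals <- array(rnorm(125), dim = c(5, 5, 5))
  pot <- valueGrid(vals, spacing = 2)
  mask <- zeroGrid(c(5, 5, 5), spacing = 2)
  forb <- gridForbidden(mask)
  forb[4, 4, 4] <- TRUE
  mask@forbidden <- forb
  probe <- Probe(rbind(c(0.8, 0, 0), c(-0.8, 0, 0)), charges = c(1, -1))

  rots <- rotationSet(5, seed = 10)
  sc1 <- probeScan(pot, mask, probe, scanConfig(mode = "min"),
                   rotations = rots)
  sc2 <- probeScan(pot, mask, probe, scanConfig(mode = "min"),
                   rotations = rev(rots))
  expect_equal(gridValues(sc1), gridValues(sc2))
  expect_true(gridForbidden(sc1)[4, 4, 4])

  # scaling all probe charges by s > 0 scales min-mode energies by s
  probeS <- Probe(rbind(c(0.8, 0, 0), c(-0.8, 0, 0)), charges = 3 * c(1, -1))
  scS <- probeScan(pot, mask, probeS,
                   scanConfig(nRotations = 5, mode = "min", seed = 10))
  fin <- is.finite(gridValues(sc1)) & !gridForbidden(sc1)
  expect_equal(gridValues(scS)[fin], 3 * gridValues(sc1)[fin],
               tolerance = 1e-9)
})
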