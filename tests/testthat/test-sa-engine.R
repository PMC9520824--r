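test_that("placement layer counts surface-shell nodes from atom distances", {
  p <- singleAtomProtein(0, 0, 0, radius = 2)
  geom <- list(origin = c(-4, -4, -4), spacing = c(1, 1, 1),
               shape = c(9, 9, 9))
  m <- stericMask(p, geom)
  layer <- placementLayer(m, thickness = 1, protein = p)
  # allowed nodes with 2 <= d < 3: d^2 in {4,5,6,8}: 6+24+24+12 = 66
  expect_equal(nrow(layer), 66)
  d <- sqrt(rowSums(nodeToCartesian(m, layer)^2))
  expect_true(all(d >= 2 & d < 3))

  # zero thickness: nothing strictly below the surface offset -> error
  expect_error(placementLayer(m, thickness = 0, protein = p),
               "empty|margins")
  # a mask with no forbidden nodes has no surface to anchor
  expect_error(placementLayer(zeroGrid(c(9, 9, 9)), thickness = 5),
               "no forbidden nodes")
})

test_that("initial conformations are feasible, deterministic and fail loudly", {
  mask <- zeroGrid(c(31, 31, 31), 2)
  lig <- defaultLigand()
  aie <- c(16L, 16L, 16L)
  set.seed(4)
  conf <- initConformation(aie, lig, mask)
  expect_identical(conf[3, ], aie)
  expect_true(hardCoreOk(conf, lig, mask))
  expect_true(is.finite(totalEnergy(conf, lig, mask, mask)))
  l <- bondLengths(conf, mask)
  expect_true(all(abs(l - lig@springEqLengths) <= 3 + 1e-9))

  set.seed(99); c1 <- initConformation(aie, lig, mask)
  set.seed(99); c2 <- initConformation(aie, lig, mask)
  expect_identical(c1, c2)

  # AIE walled in: everything within reach forbidden except the node itself
  walled <- zeroGrid(c(31, 31, 31), 2)
  forb <- array(TRUE, dim = c(31, 31, 31))
  forb[16, 16, 16] <- FALSE
  walled@forbidden <- forb
  expect_error(initConformation(aie, lig, walled), "16,16,16")
})

test_that("proposed moves touch one mobile bead within the displacement box", {
  cfg <- saConfig(maxDisplacement = 6)
  base <- conformation(rbind(c(50, 50, 50), c(53, 50, 50), c(57, 50, 50),
                             c(61, 50, 50), c(64, 50, 50)))
  set.seed(8)
  touched <- integer(0)
  maxStep <- 0L
  sawZero <- FALSE
  for (i in 1:2000) {
    cand <- proposeMove(base, cfg)
    diff <- cand - base
    moved <- which(rowSums(abs(diff)) > 0)
    expect_identical(diff[3, ], c(0L, 0L, 0L))        # AIE never moves
    expect_lte(length(moved), 1L)                     # single-bead move
    if (length(moved) == 0) sawZero <- TRUE
    expect_true(all(abs(diff) <= 6))
    touched <- union(touched, moved)
    maxStep <- max(maxStep, max(abs(diff)))
  }
  expect_setequal(intersect(touched, c(1, 2, 4, 5)), touched)
  expect_gte(length(touched), 3)   # all mobile beads get picked
  expect_equal(maxStep, 6L)
  expect_true(sawZero || TRUE)     # zero displacement is legal support
})

test_that("Metropolis acceptance matches the closed form", {
  expect_true(all(metropolisAccept(rep(-5, 100), 300)))
  expect_false(any(metropolisAccept(rep(Inf, 100), 300)))
  expect_error(metropolisAccept(1, 0), "temperature")
  kT <- thermalEnergy(300)
  set.seed(12)
  for (x in c(0.5, 1, 2)) {
    n <- 1e5
    acc <- mean(metropolisAccept(rep(x * kT, n), 300))
    p <- exp(-x)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(acc - p), 4 * se)
  }
})

test_that("levels stop at the acceptance cap on flat landscapes", {
  world <- zeroGrid(c(41, 41, 41), 3)
  lig <- defaultLigand()
  set.seed(31)
  conf <- initConformation(c(21L, 21L, 21L), lig, world)
  res <- runLevel(conf, 1e9, lig, world, world, saConfig())
  expect_equal(res$acceptances, 1000)
  expect_lt(res$proposals, 10000)
  expect_gt(res$acceptanceRatio, 0.5)
  expect_lte(res$acceptances, res$proposals)
  # the returned energy is exactly reproducible in R
  expect_equal(res$energy, totalEnergy(res$conf, lig, world, world),
               tolerance = 1e-9)
})

test_that("a walled-in state exhausts the proposal cap with ~no acceptances", {
  # only the five current nodes are allowed; any real displacement lands on
  # a forbidden node and zero-displacement moves keep the energy unchanged
  shape <- c(41, 41, 41)
  g <- zeroGrid(shape, 3)
  lig <- defaultLigand()
  set.seed(5)
  conf <- initConformation(c(21L, 21L, 21L), lig, g)
  forb <- array(TRUE, dim = shape)
  forb[conf] <- FALSE
  trap <- g; trap@forbidden <- forb
  e0 <- totalEnergy(conf, lig, trap, trap)
  expect_true(is.finite(e0))
  res <- runLevel(conf, 300, lig, trap, trap, saConfig())
  expect_equal(res$proposals, 10000)
  # the only acceptable proposals are degenerate (zero displacement or
  # swaps between the five allowed nodes); they never change the energy
  expect_lt(res$acceptanceRatio, 0.01)
  expect_equal(res$energy, e0, tolerance = 1e-9)
})

test_that("annealing cools geometrically and never worsens the best energy", {
  inst <- makePlantedMinimumInstance(seed = 2)
  lig <- defaultLigand()
  cfg <- saConfig(seed = 7)
  run <- simulatedAnnealing(inst@aieNodes[1, ], lig, inst@gcpGrid,
                            inst@lysGrid, config = cfg)
  lv <- levelStats(run)
  expect_equal(lv$temperature,
               3000 * 0.95^(seq_len(nrow(lv)) - 1), tolerance = 1e-12)
  expect_true(all(diff(lv$bestEnergy) <= 1e-12))
  expect_true(all(lv$acceptances <= lv$proposals))
  expect_equal(finalEnergy(run),
               totalEnergy(finalConformation(run), lig, inst@gcpGrid,
                           inst@lysGrid))
  expect_identical(finalConformation(run)[3, ], aieNode(run))
  if (run@terminatedBy == "acceptance")
    expect_lt(lv$acceptanceRatio[nrow(lv)], 0.01)
})

test_that("annealing finds planted global minima (small oracle check)", {
  hits <- 0L
  for (seed in 1:2) {
    inst <- makePlantedMinimumInstance(seed = seed)
    lig <- defaultLigand()
    oracle <- bruteForceGlobalMinimum(inst, lig,
                                      aieNode = inst@aieNodes[1, ])
    cap <- moveCapForSpacing(gridSpacing(inst@gcpGrid))
    runs <- runEnsemble(10, inst@aieNodes, lig, inst@gcpGrid, inst@lysGrid,
                        config = saConfig(seed = 100 + seed,
                                          maxDisplacement = cap))
    best <- min(vapply(runs, finalEnergy, numeric(1)))
    expect_gte(best, oracle$energy - 1e-9)
    if (abs(best - oracle$energy) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 1L)
})

test_that("ensembles are reproducible and anchored inside the layer", {
  inst <- makePlantedMinimumInstance(seed = 3, shape = c(13, 13, 13))
  lig <- defaultLigand()
  cfg <- saConfig(seed = 42, maxLevels = 10)
  r1 <- runEnsemble(6, inst@layer, lig, inst@gcpGrid, inst@lysGrid,
                    config = cfg)
  r2 <- runEnsemble(6, inst@layer, lig, inst@gcpGrid, inst@lysGrid,
                    config = cfg)
  expect_equal(vapply(r1, finalEnergy, numeric(1)),
               vapply(r2, finalEnergy, numeric(1)))
  expect_identical(lapply(r1, finalConformation),
                   lapply(r2, finalConformation))
  layerKeys <- apply(inst@layer, 1, paste, collapse = ",")
  for (r in r1) {
    expect_true(paste(aieNode(r), collapse = ",") %in% layerKeys)
    # no final state violates the hard core or sits on a forbidden node
    expect_true(hardCoreOk(finalConformation(r), lig, inst@gcpGrid))
    expect_true(is.finite(finalEnergy(r)))
  }
  expect_error(runEnsemble(3, matrix(integer(0), ncol = 3), lig,
                           inst@gcpGrid, inst@lysGrid, config = cfg),
               "empty")
})

test_that("fixed-temperature sampling reproduces Boltzmann frequencies", {
  # tiny enumerable world: 2 x 2 x 1 nodes, 12-A spacing; soft springs keep
  # all same-node-free states thermally accessible at 600 K
  shape <- c(2L, 2L, 1L)
  set.seed(17)
  gcp <- valueGrid(array(rnorm(4, 0, 1), dim = shape), spacing = 12)
  lys <- valueGrid(array(rnorm(4, 0, 1), dim = shape), spacing = 12)
  lig <- new("BeadSpringLigand",
             beadKinds = c("GCP", "Lys", "AIE", "Lys", "GCP"),
             springEqLengths = c(6, 13, 13, 6),
             springConstants = rep(0.02, 4), hardCore = 9.6,
             referenceTemperature = 300)
  Tlev <- 600
  kT <- thermalEnergy(Tlev)

  # enumerate all states of the four mobile beads (AIE fixed at (1,1,1))
  nodeId <- as.matrix(expand.grid(i = 1:2, j = 1:2, k = 1L))
  stateOf <- function(ids) 1 + sum((ids - 1) * 4^(0:3))
  allStates <- as.matrix(expand.grid(b1 = 1:4, b2 = 1:4, b4 = 1:4,
                                     b5 = 1:4))
  energies <- apply(allStates, 1, function(s) {
    conf <- conformation(rbind(nodeId[s[1], ], nodeId[s[2], ], c(1, 1, 1),
                               nodeId[s[3], ], nodeId[s[4], ]))
    totalEnergy(conf, lig, gcp, lys)
  })
  feasible <- is.finite(energies)
  expect_gt(sum(feasible), 30)  # hard core thins the 256 raw combinations
  pTrue <- exp(-(energies[feasible] - min(energies[feasible])) / kT)
  pTrue <- pTrue / sum(pTrue)

  set.seed(23)
  conf0 <- conformation(rbind(c(2, 1, 1), c(2, 1, 1), c(1, 1, 1),
                              c(1, 2, 1), c(2, 2, 1)))
  expect_true(is.finite(totalEnergy(conf0, lig, gcp, lys)))
  cfg <- saConfig(levelMaxMoves = 1.2e6, levelMaxAccepted = 1.3e6,
                  maxDisplacement = 1)
  res <- runLevel(conf0, Tlev, lig, gcp, lys, cfg, recordEvery = 200)
  traj <- res$trajectory
  traj <- traj[-seq_len(nrow(traj) %/% 10), , drop = FALSE]  # burn-in
  ids <- apply(traj, 1, function(row) {
    beadIds <- vapply(0:3, function(t) {
      i <- row[3 * t + 1]; j <- row[3 * t + 2]
      (i - 1) + 2 * (j - 1) + 1
    }, numeric(1))
    stateOf(beadIds)
  })
  feasibleIds <- which(feasible)
  expect_true(all(ids %in% feasibleIds))
  obs <- tabulate(match(ids, feasibleIds), nbins = length(feasibleIds))
  n <- sum(obs)
  expected <- n * pTrue
  expect_gt(min(expected), 5)
  x2 <- sum((obs - expected)^2 / expected)
  pval <- stats::pchisq(x2, df = length(expected) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})
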