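#' Synthetic toy protein
#'
#' Deterministic (seeded) generators for small PQR-writable structures used
#' to exercise the whole stack without external data: atoms on a sphere
#' shell, on a plane lattice, or in two lobes that are exactly C2-symmetric
#' about a declared axis (the axis is stored in the structure's metadata).
#'
#' @param nAtoms Number of atoms (two_lobes uses `nAtoms` per lobe).
#' @param arrangement `"sphere"`, `"plane"` or `"two_lobes"`.
#' @param chargePattern Numeric vector recycled over atoms (per lobe for
#'   `two_lobes`, so the pattern preserves the symmetry).
#' @param seed RNG seed.
#' @param radius van der Waals radius given to every atom, Angstrom.
#' @param extent Characteristic size, Angstrom (sphere radius, plane
#'   half-width, lobe center offset).
#' @return A [ProteinStructure-class]; for `two_lobes` the metadata holds
#'   `axis = list(point, direction)`.
#' @export
makeToyProtein <- function(nAtoms, arrangement = c("sphere", "plane",
                                                   "two_lobes"),
                           chargePattern = c(1, -1), seed = 1,
                           radius = 1.7, extent = 8) {
  stopifnot(nAtoms >= 1)
  arrangement <- match.arg(arrangement)
  metadata <- list()
  xyz <- .withSeed(seed, switch(arrangement,
    sphere = {
      # Fibonacci sphere: quasi-uniform, deterministic
      i <- seq_len(nAtoms) - 0.5
      phi <- acos(1 - 2 * i / nAtoms)
      theta <- pi * (1 + sqrt(5)) * i
      extent * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
    },
    plane = {
      side <- ceiling(sqrt(nAtoms))
      g <- as.matrix(expand.grid(seq_len(side), seq_len(side)))[seq_len(nAtoms), ,
                                                                drop = FALSE]
      step <- 2 * extent / max(1, side - 1)
      cbind((g[, 1] - (side + 1) / 2) * step,
            (g[, 2] - (side + 1) / 2) * step, 0)
    },
    two_lobes = {
      lobe <- matrix(stats::runif(3 * nAtoms, -extent / 2, extent / 2),
                     ncol = 3)
      lobe[, 1] <- lobe[, 1] + extent
      rbind(lobe, cbind(-lobe[, 1], -lobe[, 2], lobe[, 3]))
    }))
  if (arrangement == "two_lobes")
    metadata$axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  n <- nrow(xyz)
  charges <- rep_len(chargePattern,
                     if (arrangement == "two_lobes") nAtoms else n)
  if (arrangement == "two_lobes") charges <- rep(charges, 2)
  ProteinStructure(data.frame(
    record = "ATOM", serial = seq_len(n), name = "C", resname = "TOY",
    chain = "A", resid = seq_len(n), x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], charge = charges, radius = radius,
    stringsAsFactors = FALSE), metadata = metadata)
}

# Mirror a node matrix under the lattice C2 map (i,j,k) -> (n1+1-i, n2+1-j, k)
.mirrorNodes <- function(nodes, shape) {
  cbind(shape[1] + 1L - nodes[, 1], shape[2] + 1L - nodes[, 2], nodes[, 3])
}

# Exactly symmetrize a 3-D array under the lattice C2 map by copying the
# value of each node's canonical partner (keeps the marginal noise scale).
.symmetrizeArray <- function(arr) {
  d <- dim(arr)
  nodes <- .allNodes(d)
  mirror <- .mirrorNodes(nodes, d)
  lin <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  a <- lin(nodes); b <- lin(mirror)
  copy <- b < a
  arr[a[copy]] <- arr[b[copy]]
  arr
}

# Add a Gaussian well (depth < 0, half-width one node) around `node`.
.addWell <- function(values, spacing, node, depth) {
  d <- dim(values)
  rad <- 3L
  rng <- lapply(1:3, function(ax) max(1, node[ax] - rad):min(d[ax], node[ax] + rad))
  box <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  d2 <- ((box[, 1] - node[1]) * spacing[1])^2 +
        ((box[, 2] - node[2]) * spacing[2])^2 +
        ((box[, 3] - node[3]) * spacing[3])^2
  s2 <- mean(spacing)^2
  values[box] <- values[box] + depth * exp(-d2 / (2 * s2))
  values
}

#' Synthetic planted-minimum instance
#'
#' Builds a complete, self-contained test system: a small convex toy
#' protein carves a steric mask at the grid center; the GCP and Lys
#' affinity grids are zero-mean Gaussian background noise plus Gaussian
#' wells (half-width one node) planted at nodes that the default ligand can
#' reach from the recorded AIE anchor nodes (spring-compatible distances,
#' hard-core-compatible separations). With `c2Mirror = TRUE` the protein,
#' the noise, the wells and the anchors are all exactly symmetric under a
#' 180-degree rotation about the z axis through the grid center.
#'
#' The planted wells mark the intended global-minimum region; the exact
#' optimum (including discretization spring strain and noise) is computed
#' by [bruteForceGlobalMinimum()].
#'
#' @param shape Node counts per axis (odd values keep the center on a
#'   node).
#' @param spacing Grid spacing, Angstrom.
#' @param noiseSigma Standard deviation of the background noise, kJ/mol.
#' @param wellDepth Length-2 vector: depths (negative, kJ/mol) of the GCP
#'   and Lys wells.
#' @param seed RNG seed; also jitters depths and picks the arm orientation.
#' @param c2Mirror Make the instance exactly C2-symmetric?
#' @param ligand The ligand the minima must be compatible with.
#' @return A [PlantedInstance-class].
#' @export
makePlantedMinimumInstance <- function(shape = c(15, 15, 15), spacing = 3,
                                       noiseSigma = 0.5,
                                       wellDepth = c(gcp = -60, lys = -60),
                                       seed = 1, c2Mirror = FALSE,
                                       ligand = defaultLigand()) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(spacing, 3)
  origin <- -spacing * (shape - 1) / 2
  geom <- list(origin = origin, spacing = spacing, shape = shape)

  # compact symmetric blob at the center
  blob <- rbind(c(0, 0, 0), 2 * diag(3), -2 * diag(3))
  protein <- ProteinStructure(data.frame(
    record = "ATOM", serial = seq_len(nrow(blob)), name = "C",
    resname = "BLB", chain = "A", resid = seq_len(nrow(blob)),
    x = blob[, 1], y = blob[, 2], z = blob[, 3], charge = 0, radius = 3,
    stringsAsFactors = FALSE),
    metadata = list(axis = list(point = c(0, 0, 0), direction = c(0, 0, 1))))
  mask <- stericMask(protein, geom)

  # template arm layout (node offsets from the grid center, exact on the
  # lattice): AIE anchor at +2 e1; Lys wells at ~12 A, GCP wells at 6 A
  # from their Lys, all non-bonded separations >= a = 9.6 A
  ctr <- (shape + 1L) %/% 2L
  tmplA <- c(2L, 0L, 0L)
  tmplLys <- rbind(c(6L, 0L, 0L), c(2L, 4L, 0L))
  tmplGcp <- rbind(c(6L, 2L, 0L), c(2L, 6L, 0L))

  inst <- .withSeed(seed, {
    # seeded variation: one of four exact lattice rotations about z,
    # +-20% depth jitter
    rot <- sample(0:3, 1)
    rotNodes <- function(m) {
      m <- matrix(m, ncol = 3)
      for (r in seq_len(rot)) m[, 1:2] <- cbind(-m[, 2], m[, 1])
      m
    }
    offCtr <- function(m) sweep(rotNodes(m), 2, ctr, "+")
    aieNodes <- offCtr(tmplA)
    lysNodes <- offCtr(tmplLys)
    gcpNodes <- offCtr(tmplGcp)
    depths <- list(gcp = wellDepth[1] * stats::runif(2, 0.8, 1.2),
                   lys = wellDepth[2] * stats::runif(2, 0.8, 1.2))
    if (c2Mirror) {
      aieNodes <- rbind(aieNodes, .mirrorNodes(aieNodes, shape))
      lysNodes <- rbind(lysNodes, .mirrorNodes(lysNodes, shape))
      gcpNodes <- rbind(gcpNodes, .mirrorNodes(gcpNodes, shape))
      depths$gcp <- rep(depths$gcp, 2)
      depths$lys <- rep(depths$lys, 2)
    }
    gcpVals <- array(stats::rnorm(prod(shape), 0, noiseSigma), dim = shape)
    lysVals <- array(stats::rnorm(prod(shape), 0, noiseSigma), dim = shape)
    if (c2Mirror) {
      gcpVals <- .symmetrizeArray(gcpVals)
      lysVals <- .symmetrizeArray(lysVals)
    }
    for (i in seq_len(nrow(gcpNodes)))
      gcpVals <- .addWell(gcpVals, spacing, gcpNodes[i, ], depths$gcp[i])
    for (i in seq_len(nrow(lysNodes)))
      lysVals <- .addWell(lysVals, spacing, lysNodes[i, ], depths$lys[i])
    if (c2Mirror) {
      # enforce bit-exact symmetry (well sums can differ by rounding order)
      gcpVals <- .symmetrizeArray(gcpVals)
      lysVals <- .symmetrizeArray(lysVals)
    }
    list(aieNodes = aieNodes, lysNodes = lysNodes, gcpNodes = gcpNodes,
         depths = depths, gcpVals = gcpVals, lysVals = lysVals)
  })

  forb <- mask@forbidden
  gcpGrid <- ScalarGrid(inst$gcpVals, origin, spacing, forbidden = forb)
  lysGrid <- ScalarGrid(inst$lysVals, origin, spacing, forbidden = forb)

  # geometric consistency of the planted layout with the ligand
  planted <- conformation(rbind(inst$gcpNodes[1, ], inst$lysNodes[1, ],
                                inst$aieNodes[1, ], inst$lysNodes[2, ],
                                inst$gcpNodes[2, ]))
  if (!all(.inBounds(shape, planted)))
    stop("inconsistent geometry: planted nodes fall outside the grid")
  if (any(mask@forbidden[planted]))
    stop("inconsistent geometry: planted nodes are sterically forbidden")
  if (!hardCoreOk(planted, ligand, gcpGrid))
    stop("inconsistent geometry: planted layout violates the hard core")
  l <- bondLengths(planted, gcpGrid)
  if (any(abs(l - ligand@springEqLengths) > 3))
    stop("inconsistent geometry: planted bonds too strained (",
         paste(signif(l, 3), collapse = ", "), " A)")

  layer <- placementLayer(mask, thickness = sum(ligand@springEqLengths[1:2]),
                          protein = protein)
  # keep only layer nodes from which a feasible start exists
  feasible <- vapply(seq_len(nrow(layer)), function(i) {
    ok <- TRUE
    tryCatch(.withSeed(seed + i,
                       initConformation(layer[i, ], ligand, mask,
                                        maxTries = 60)),
             error = function(e) ok <<- FALSE)
    ok
  }, logical(1))
  layer <- layer[feasible, , drop = FALSE]
  if (nrow(layer) == 0)
    stop("no feasible layer nodes; enlarge the grid")

  new("PlantedInstance", gcpGrid = gcpGrid, lysGrid = lysGrid, mask = mask,
      minima = list(gcpNodes = .asNodeMatrix(inst$gcpNodes),
                    lysNodes = .asNodeMatrix(inst$lysNodes),
                    gcpDepths = inst$depths$gcp,
                    lysDepths = inst$depths$lys),
      protein = protein, aieNodes = .asNodeMatrix(inst$aieNodes),
      layer = .asNodeMatrix(layer),
      axis = if (c2Mirror) list(point = c(0, 0, 0), direction = c(0, 0, 1))
             else list())
}

#' Exact global minimum by exhaustive enumeration
#'
#' Independent brute-force oracle for the annealing search: with the AIE
#' bead fixed, enumerates every conformation whose Lys beads lie within
#' `reachPad` of their equilibrium distance from the AIE and whose GCP
#' beads lie within `reachPad` of equilibrium from some Lys candidate, and
#' returns the exact minimum of the total energy over that feasible set
#' (hard core included). The two chain arms are enumerated separately and
#' combined in best-first order with an exact early-exit bound.
#'
#' Exactness is relative to the enumerated set: a minimum further than
#' `reachPad` from spring equilibrium is not considered, so `reachPad`
#' should be chosen so that the spring strain at the shell edge exceeds any
#' achievable affinity gain (for the default ligand, strain at 3 A
#' deviation is already ~34 kJ/mol on a Lys-AIE bond and ~135 kJ/mol on a
#' GCP-Lys bond).
#'
#' @param instance A [PlantedInstance-class] (or pass grids via
#'   `gcpGrid`/`lysGrid`).
#' @param ligand [BeadSpringLigand-class].
#' @param aieNode AIE anchor node (1-based triple).
#' @param reachPad Shell half-width around spring equilibrium, Angstrom.
#' @param maxCandidates Per-bead candidate-set cap; exceeding it raises an
#'   error advising coarser spacing.
#' @param gcpGrid,lysGrid Used when `instance` is NULL.
#' @return `list(energy, conformation)`.
#' @export
bruteForceGlobalMinimum <- function(instance = NULL, ligand = defaultLigand(),
                                    aieNode, reachPad = 3,
                                    maxCandidates = 2000,
                                    gcpGrid = NULL, lysGrid = NULL) {
  if (!is.null(instance)) {
    gcpGrid <- instance@gcpGrid
    lysGrid <- instance@lysGrid
  }
  stopifnot(is(gcpGrid, "ScalarGrid"), is(lysGrid, "ScalarGrid"))
  mask <- gcpGrid
  mask@forbidden <- gcpGrid@forbidden | lysGrid@forbidden
  aieNode <- as.integer(aieNode)
  aieXYZ <- as.vector(nodeToCartesian(mask, aieNode))
  leq <- ligand@springEqLengths
  k <- ligand@springConstants
  a2 <- ligand@hardCore^2
  lysVal <- function(m) lysGrid@values[m]
  gcpVal <- function(m) gcpGrid@values[m]
  linIdx <- function(m) cbind(m[, 1], m[, 2], m[, 3])

  armCandidates <- function(lysEq, lysK, gcpEq, gcpK) {
    lysCand <- .shellNodes(mask, aieXYZ, lysEq - reachPad, lysEq + reachPad)
    if (nrow(lysCand) == 0) stop("no Lys candidates within reach of the AIE")
    if (nrow(lysCand) > maxCandidates)
      stop("candidate set too large (", nrow(lysCand),
           " Lys nodes); use coarser spacing or smaller reachPad")
    lysXYZ <- nodeToCartesian(mask, lysCand)
    dLys <- sqrt(rowSums(sweep(lysXYZ, 2, aieXYZ, "-")^2))
    eLysSpring <- 0.5 * lysK * (dLys - lysEq)^2
    eLysGrid <- lysVal(linIdx(lysCand))

    rows <- list()
    for (li in seq_len(nrow(lysCand))) {
      gc <- .shellNodes(mask, lysXYZ[li, ], gcpEq - reachPad,
                        gcpEq + reachPad)
      if (nrow(gc) == 0) next
      if (nrow(gc) > maxCandidates)
        stop("candidate set too large (", nrow(gc),
             " GCP nodes); use coarser spacing or smaller reachPad")
      gXYZ <- nodeToCartesian(mask, gc)
      # hard core: GCP vs AIE (non-bonded pair)
      okHC <- rowSums(sweep(gXYZ, 2, aieXYZ, "-")^2) >= a2
      if (!any(okHC)) next
      gc <- gc[okHC, , drop = FALSE]
      gXYZ <- gXYZ[okHC, , drop = FALSE]
      dG <- sqrt(rowSums(sweep(gXYZ, 2, lysXYZ[li, ], "-")^2))
      e <- eLysSpring[li] + eLysGrid[li] + 0.5 * gcpK * (dG - gcpEq)^2 +
        gcpVal(linIdx(gc))
      rows[[length(rows) + 1]] <-
        cbind(lys = matrix(rep(lysCand[li, ], each = nrow(gc)), ncol = 3),
              gcp = gc, lysXYZ = matrix(rep(lysXYZ[li, ], each = nrow(gc)),
                                        ncol = 3),
              gcpXYZ = gXYZ, energy = e)
    }
    if (!length(rows)) stop("no feasible arm configurations")
    arm <- do.call(rbind, rows)
    arm[order(arm[, 13]), , drop = FALSE]
  }

  arm1 <- armCandidates(leq[2], k[2], leq[1], k[1])
  arm2 <- armCandidates(leq[3], k[3], leq[4], k[4])

  best <- Inf
  bestPair <- NULL
  e2 <- arm2[, 13]
  minE2 <- e2[1]
  for (i in seq_len(nrow(arm1))) {
    e1 <- arm1[i, 13]
    if (e1 + minE2 >= best) break
    nj <- findInterval(best - e1, e2)
    if (nj < 1) next
    sub <- arm2[seq_len(nj), , drop = FALSE]
    # cross hard core: Lys1-Lys2, Lys1-GCP2, GCP1-Lys2, GCP1-GCP2
    l1 <- arm1[i, 7:9]; g1 <- arm1[i, 10:12]
    ok <- rowSums(sweep(sub[, 7:9, drop = FALSE], 2, l1, "-")^2) >= a2 &
          rowSums(sweep(sub[, 10:12, drop = FALSE], 2, l1, "-")^2) >= a2 &
          rowSums(sweep(sub[, 7:9, drop = FALSE], 2, g1, "-")^2) >= a2 &
          rowSums(sweep(sub[, 10:12, drop = FALSE], 2, g1, "-")^2) >= a2
    if (!any(ok)) next
    tot <- e1 + sub[ok, 13]
    j <- which.min(tot)
    if (tot[j] < best) {
      best <- tot[j]
      bestPair <- list(arm1 = arm1[i, ], arm2 = sub[ok, , drop = FALSE][j, ])
    }
  }
  if (is.null(bestPair))
    stop("no feasible conformation in the enumerated set")
  conf <- conformation(rbind(bestPair$arm1[4:6], bestPair$arm1[1:3],
                             aieNode, bestPair$arm2[1:3], bestPair$arm2[4:6]))
  # report the energy through the reference implementation for consistency
  list(energy = totalEnergy(conf, ligand, gcpGrid, lysGrid),
       conformation = conf)
}

#' Write reference (production) configuration files
#'
#' Emits a YAML config encoding the production parameters: 0.4 A grid
#' spacing, 150 probe rotations, 0.1 M NaCl + 0.01 M MgCl2 with
#' permittivities 2 (protein) and 79 (water), the default ligand (6, 13,
#' 13, 6 A; 12, 3, 3, 12 kBT/A^2; a = 9.6 A at 300 K), and the annealing
#' schedule (3000 K start, 10000/1000 level caps, 1% stop, 6-grid-length
#' moves, 4000 runs).
#'
#' @param outdir Writable output directory.
#' @return Invisibly, the path of the written config file.
#' @seealso [readConfig()]
#' @export
makeReferenceConfigs <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  cfg <- list(
    grid = list(spacing = 0.4),
    scan = list(n_rotations = 150L, mode = "boltzmann", temperature = 300),
    solvent = list(
      species = list(
        list(name = "Na+", concentration = 0.1, valence = 1L),
        list(name = "Cl-", concentration = 0.12, valence = -1L),
        list(name = "Mg2+", concentration = 0.01, valence = 2L)),
      eps_water = 79, eps_protein = 2, temperature = 300),
    ligand = list(
      bead_kinds = c("GCP", "Lys", "AIE", "Lys", "GCP"),
      spring_eq_lengths = c(6, 13, 13, 6),
      spring_constants = c(12, 3, 3, 12),
      spring_constant_units = "kBT/A2",
      hard_core = 9.6,
      reference_temperature = 300),
    annealing = list(
      t0 = 3000, cooling_factor = 0.95, level_max_moves = 10000L,
      level_max_accepted = 1000L, stop_acceptance = 0.01,
      max_displacement = 6L, max_levels = 200L, n_runs = 4000L))
  path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a structured configuration file
#'
#' Parses a YAML config (see [makeReferenceConfigs()] for the layout) into
#' typed objects. Ligand spring constants may be given in `kBT/A2`
#' (converted at the ligand's reference temperature) or `kJ/molA2`.
#'
#' @param path Path to the YAML config.
#' @return `list(ligand, solvent, scan, annealing, nRuns, spacing)`.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lig <- cfg$ligand
  refT <- lig$reference_temperature %||% 300
  kConv <- if (identical(lig$spring_constant_units, "kBT/A2"))
    thermalEnergy(refT) else 1
  ligand <- new("BeadSpringLigand",
                beadKinds = as.character(lig$bead_kinds),
                springEqLengths = as.numeric(lig$spring_eq_lengths),
                springConstants = as.numeric(lig$spring_constants) * kConv,
                hardCore = as.numeric(lig$hard_core),
                referenceTemperature = refT)
  sol <- cfg$solvent
  species <- do.call(rbind, lapply(sol$species, function(s)
    data.frame(concentration = s$concentration, valence = s$valence)))
  solvent <- ionicSolvent(species, epsWater = sol$eps_water %||% 79,
                          epsProtein = sol$eps_protein %||% 2,
                          temperature = sol$temperature %||% 300)
  sc <- cfg$scan
  scan <- scanConfig(nRotations = sc$n_rotations %||% 150,
                     mode = sc$mode %||% "boltzmann",
                     temperature = sc$temperature %||% 300)
  an <- cfg$annealing
  annealing <- saConfig(
    t0 = an$t0 %||% 3000, coolingFactor = an$cooling_factor %||% 0.95,
    levelMaxMoves = an$level_max_moves %||% 10000,
    levelMaxAccepted = an$level_max_accepted %||% 1000,
    stopAcceptance = an$stop_acceptance %||% 0.01,
    maxDisplacement = an$max_displacement %||% 6,
    maxLevels = an$max_levels %||% 200)
  list(ligand = ligand, solvent = solvent, scan = scan,
       annealing = annealing, nRuns = an$n_runs %||% 4000L,
       spacing = cfg$grid$spacing %||% 0.4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
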