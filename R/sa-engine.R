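#' Placement layer around the protein surface
#'
#' The set of allowed nodes within a shell of the protein van der Waals
#' surface, from which AIE anchor positions are drawn. The default shell
#' thickness is the chain distance between the AIE and GCP beads
#' (13 + 6 = 19 A). When the protein is supplied, a node is in the layer
#' iff it is allowed and its surface distance `min_i(|x - x_i| - R_i)` lies
#' in `[0, thickness)`. Without a protein the surface distance is
#' approximated by the distance to the nearest forbidden node (with
#' inclusion at `<= thickness`), which is coarser by up to one node
#' diagonal.
#'
#' @param mask [ScalarGrid-class] carrying the steric mask.
#' @param thickness Shell thickness, Angstrom.
#' @param protein Optional [ProteinStructure-class] that carved the mask.
#' @return Integer `n x 3` matrix of layer node indices.
#' @export
placementLayer <- function(mask, thickness = 19, protein = NULL) {
  stopifnot(is(mask, "ScalarGrid"), thickness >= 0)
  shape <- dim(mask@values)
  if (!any(mask@forbidden))
    stop("mask has no forbidden nodes: no protein surface to anchor the layer")
  nodes <- .allNodes(shape)
  allowed <- !as.vector(mask@forbidden)
  xyz <- nodeToCartesian(mask, nodes)
  if (!is.null(protein)) {
    a <- protein@atoms
    sdist <- rep(Inf, nrow(nodes))
    for (i in seq_len(nrow(a))) {
      d <- sqrt((xyz[, 1] - a$x[i])^2 + (xyz[, 2] - a$y[i])^2 +
                (xyz[, 3] - a$z[i])^2) - a$radius[i]
      sdist <- pmin(sdist, d)
    }
    inLayer <- allowed & sdist >= 0 & sdist < thickness
  } else {
    fxyz <- xyz[!allowed, , drop = FALSE]
    sdist <- rep(Inf, nrow(nodes))
    chunk <- max(1L, floor(2e6 / max(1, nrow(fxyz))))
    aIdx <- which(allowed)
    for (start in seq(1L, length(aIdx), by = chunk)) {
      rows <- aIdx[start:min(start + chunk - 1L, length(aIdx))]
      d2 <- outer(xyz[rows, 1], fxyz[, 1], "-")^2 +
            outer(xyz[rows, 2], fxyz[, 2], "-")^2 +
            outer(xyz[rows, 3], fxyz[, 3], "-")^2
      sdist[rows] <- sqrt(apply(d2, 1, min))
    }
    inLayer <- allowed & sdist <= thickness
  }
  if (!any(inLayer))
    stop("placement layer is empty; enlarge the grid margins around the protein")
  .asNodeMatrix(nodes[inLayer, , drop = FALSE])
}

# Offset stencils for spherical shells are cached per (spacing, lo, hi):
# the same ligand reach is queried thousands of times per instance.
.shellCache <- new.env(parent = emptyenv())

.shellStencil <- function(spacing, lo, hi) {
  key <- paste(signif(c(spacing, lo, hi), 12), collapse = "|")
  hit <- .shellCache[[key]]
  if (!is.null(hit)) return(hit)
  rad <- max(ceiling(hi / spacing)) + 1L
  box <- as.matrix(expand.grid(i = -rad:rad, j = -rad:rad, k = -rad:rad,
                               KEEP.OUT.ATTRS = FALSE))
  d <- sqrt((box[, 1] * spacing[1])^2 + (box[, 2] * spacing[2])^2 +
            (box[, 3] * spacing[3])^2)
  out <- box[d >= lo & d <= hi, , drop = FALSE]
  .shellCache[[key]] <- out
  out
}

# Allowed nodes whose Cartesian distance to `centerXYZ` lies in [lo, hi].
# centerXYZ must be a node center for the stencil path to be exact.
.shellNodes <- function(mask, centerXYZ, lo, hi) {
  shape <- dim(mask@values)
  ctrIdx <- round((centerXYZ - mask@origin) / mask@spacing) + 1
  onNode <- max(abs(mask@origin + (ctrIdx - 1) * mask@spacing -
                    centerXYZ)) < 1e-9
  if (onNode) {
    st <- .shellStencil(mask@spacing, lo, hi)
    box <- sweep(st, 2, as.integer(ctrIdx), "+")
  } else {
    sp <- mask@spacing
    loIdx <- pmax(1, floor((centerXYZ - mask@origin - hi) / sp) + 1)
    hiIdx <- pmin(shape, ceiling((centerXYZ - mask@origin + hi) / sp) + 1)
    if (any(loIdx > hiIdx)) return(matrix(integer(0), ncol = 3))
    box <- as.matrix(expand.grid(i = loIdx[1]:hiIdx[1],
                                 j = loIdx[2]:hiIdx[2],
                                 k = loIdx[3]:hiIdx[3],
                                 KEEP.OUT.ATTRS = FALSE))
    xyz <- nodeToCartesian(mask, box)
    d <- sqrt(rowSums(sweep(xyz, 2, centerXYZ, "-")^2))
    box <- box[d >= lo & d <= hi, , drop = FALSE]
  }
  inb <- box[, 1] >= 1 & box[, 1] <= shape[1] &
         box[, 2] >= 1 & box[, 2] <= shape[2] &
         box[, 3] >= 1 & box[, 3] <= shape[3]
  box <- box[inb, , drop = FALSE]
  if (nrow(box) == 0) return(matrix(integer(0), ncol = 3))
  forb <- mask@forbidden[cbind(box[, 1], box[, 2], box[, 3])]
  .asNodeMatrix(box[!forb, , drop = FALSE])
}

#' Random feasible initial conformation
#'
#' Places the AIE bead at `aieNode`, each Lys bead on a random allowed node
#' within `l_LysAIE +/- 3 A` of the AIE, and each GCP bead on a random
#' allowed node within `l_GCPLys +/- 3 A` of its Lys, retrying (up to
#' `maxTries`) until the hard-core constraint is satisfied. Deterministic
#' given the RNG state.
#'
#' @param aieNode Allowed grid node (1-based triple) for the AIE bead.
#' @param ligand A [BeadSpringLigand-class].
#' @param mask [ScalarGrid-class] steric mask.
#' @param maxTries Retry cap.
#' @param tolerance Half-width of the placement shells, Angstrom.
#' @return A `5 x 3` conformation matrix.
#' @export
initConformation <- function(aieNode, ligand, mask, maxTries = 1000,
                             tolerance = 3) {
  aieNode <- as.integer(aieNode)
  stopifnot(length(aieNode) == 3)
  if (mask@forbidden[aieNode[1], aieNode[2], aieNode[3]])
    stop(sprintf("AIE node (%d,%d,%d) is forbidden", aieNode[1], aieNode[2],
                 aieNode[3]))
  aieXYZ <- as.vector(nodeToCartesian(mask, aieNode))
  l <- ligand@springEqLengths
  lysShellA <- .shellNodes(mask, aieXYZ, l[2] - tolerance, l[2] + tolerance)
  lysShellB <- .shellNodes(mask, aieXYZ, l[3] - tolerance, l[3] + tolerance)
  if (nrow(lysShellA) == 0 || nrow(lysShellB) == 0)
    stop(sprintf("no feasible placement around AIE node (%d,%d,%d)",
                 aieNode[1], aieNode[2], aieNode[3]))
  for (try in seq_len(maxTries)) {
    lys1 <- lysShellA[sample.int(nrow(lysShellA), 1), ]
    lys2 <- lysShellB[sample.int(nrow(lysShellB), 1), ]
    g1Shell <- .shellNodes(mask, as.vector(nodeToCartesian(mask, lys1)),
                           l[1] - tolerance, l[1] + tolerance)
    g2Shell <- .shellNodes(mask, as.vector(nodeToCartesian(mask, lys2)),
                           l[4] - tolerance, l[4] + tolerance)
    if (nrow(g1Shell) == 0 || nrow(g2Shell) == 0) next
    gcp1 <- g1Shell[sample.int(nrow(g1Shell), 1), ]
    gcp2 <- g2Shell[sample.int(nrow(g2Shell), 1), ]
    conf <- conformation(rbind(gcp1, lys1, aieNode, lys2, gcp2))
    if (hardCoreOk(conf, ligand, mask)) return(conf)
  }
  stop(sprintf(
    "no feasible initial conformation around AIE node (%d,%d,%d) after %d tries",
    aieNode[1], aieNode[2], aieNode[3], maxTries))
}

#' Displacement cap for a given grid spacing
#'
#' The production move cap is 6 grid lengths on a 0.4-A grid, i.e. a 2.4-A
#' physical move extent. On coarser grids, keeping 6 grid lengths would
#' propose jumps of tens of Angstrom that the springs almost always veto,
#' quenching the search; this helper scales the cap to preserve the
#' physical extent instead. The floor of 2 keeps the probability of a
#' zero-displacement proposal, `1 / (2 m + 1)^3 <= 0.8%`, below the 1%
#' acceptance-ratio stop, which would otherwise never trigger.
#'
#' @param spacing Grid spacing (scalar or per-axis), Angstrom.
#' @param extent Physical move extent to preserve, Angstrom.
#' @return Integer displacement cap in grid lengths.
#' @examples
#' moveCapForSpacing(0.4)  # 6, the production value
#' moveCapForSpacing(3)    # 2, for coarse oracle-scale grids
#' @export
moveCapForSpacing <- function(spacing, extent = 2.4) {
  max(2L, as.integer(round(extent / max(spacing))))
}

#' Propose a single-bead move
#'
#' Picks one of the four mobile beads (both Lys, both GCP) uniformly and
#' displaces its node by an integer vector with each component uniform on
#' `{-maxDisplacement, ..., +maxDisplacement}`. The AIE bead never moves.
#' The candidate may be infeasible; infeasibility is handled by the
#' Metropolis step (`+Inf` energy, certain rejection).
#'
#' @param conf Current `5 x 3` conformation.
#' @param config An [SAConfig-class].
#' @return Candidate conformation.
#' @export
proposeMove <- function(conf, config = saConfig()) {
  bead <- sample(c(1L, 2L, 4L, 5L), 1)
  m <- config@maxDisplacement
  conf[bead, ] <- conf[bead, ] + sample.int(2L * m + 1L, 3, replace = TRUE) -
    (m + 1L)
  conf
}

#' Metropolis acceptance
#'
#' Accept when `deltaE <= 0`; otherwise accept with probability
#' `exp(-deltaE / (kB T))`. Infinite `deltaE` is always rejected.
#' Vectorized over `deltaE`.
#'
#' @param deltaE Energy difference(s), kJ/mol.
#' @param temperature Temperature, K (> 0).
#' @return Logical vector of acceptance decisions.
#' @export
metropolisAccept <- function(deltaE, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  n <- length(deltaE)
  p <- exp(-deltaE / thermalEnergy(temperature))
  p[deltaE <= 0] <- 1
  p[is.infinite(deltaE) & deltaE > 0] <- 0
  stats::runif(n) < p
}

#' Run one temperature level of Metropolis MCMC
#'
#' Propose/evaluate/accept until `levelMaxMoves` proposals or
#' `levelMaxAccepted` acceptances, whichever comes first. The hot loop runs
#' in compiled code with energies identical to [totalEnergy()].
#'
#' @param conf Feasible (finite-energy) starting conformation.
#' @param temperature Level temperature, K.
#' @param ligand [BeadSpringLigand-class].
#' @param gcpGrid,lysGrid Affinity grids.
#' @param config [SAConfig-class].
#' @param recordEvery If > 0, record the mobile-bead nodes every this many
#'   proposals (for diagnostics and sampling checks).
#' @return `list(conf, energy, bestEnergy, proposals, acceptances,
#'   acceptanceRatio, trajectory)`.
#' @export
runLevel <- function(conf, temperature, ligand, gcpGrid, lysGrid,
                     config = saConfig(), recordEvery = 0) {
  if (!.sameGeometry(gcpGrid, lysGrid))
    stop("gcpGrid and lysGrid geometries differ")
  forb <- gcpGrid@forbidden | lysGrid@forbidden
  res <- .run_level_cpp(conf - 1L, as.vector(gcpGrid@values),
                        as.vector(lysGrid@values), as.vector(forb),
                        dim(gcpGrid@values), gcpGrid@spacing,
                        ligand@springEqLengths, ligand@springConstants,
                        ligand@hardCore, temperature, .kB,
                        config@levelMaxMoves, config@levelMaxAccepted,
                        config@maxDisplacement, as.integer(recordEvery))
  out <- list(conf = conformation(res$conf + 1L), energy = res$energy,
              bestEnergy = res$bestEnergy, proposals = res$proposals,
              acceptances = res$acceptances,
              acceptanceRatio = res$acceptances / res$proposals)
  if (recordEvery > 0) out$trajectory <- res$trajectory + 1L
  out
}

#' One simulated-annealing run
#'
#' Anneals a randomly initialized conformation with the AIE bead fixed at
#' `aieNode`: Metropolis MCMC levels at temperatures `T0, a T0, a^2 T0, ...`
#' until a completed level's acceptance ratio falls below
#' `stopAcceptance` or `maxLevels` is reached. The reported final energy is
#' re-evaluated from the stored final conformation with [totalEnergy()].
#'
#' @param aieNode Allowed grid node for the AIE bead.
#' @param ligand [BeadSpringLigand-class].
#' @param gcpGrid,lysGrid Affinity grids.
#' @param mask Optional extra steric mask; defaults to the grids' own
#'   forbidden nodes.
#' @param config [SAConfig-class]; `config@seed` (if not NA) seeds the run.
#' @return An [SARunResult-class].
#' @export
simulatedAnnealing <- function(aieNode, ligand, gcpGrid, lysGrid,
                               mask = NULL, config = saConfig()) {
  if (is.null(mask)) {
    mask <- gcpGrid
    mask@forbidden <- gcpGrid@forbidden | lysGrid@forbidden
  } else {
    # fold the external mask into the grids so the Metropolis kernel, the
    # initializer and the final re-evaluation all see the same exclusions
    gcpGrid@forbidden <- gcpGrid@forbidden | mask@forbidden
    lysGrid@forbidden <- lysGrid@forbidden | mask@forbidden
  }
  .withSeed(if (is.na(config@seed)) NULL else config@seed, {
    conf <- initConformation(aieNode, ligand, mask)
    best <- totalEnergy(conf, ligand, gcpGrid, lysGrid)
    levels <- vector("list", config@maxLevels)
    terminated <- "max_levels"
    temp <- config@t0
    for (lvl in seq_len(config@maxLevels)) {
      res <- runLevel(conf, temp, ligand, gcpGrid, lysGrid, config)
      conf <- res$conf
      best <- min(best, res$bestEnergy)
      levels[[lvl]] <- data.frame(
        level = lvl, temperature = temp, proposals = res$proposals,
        acceptances = res$acceptances, acceptanceRatio = res$acceptanceRatio,
        bestEnergy = best)
      if (res$acceptanceRatio < config@stopAcceptance) {
        terminated <- "acceptance"
        levels <- levels[seq_len(lvl)]
        break
      }
      temp <- temp * config@coolingFactor
    }
    levels <- levels[!vapply(levels, is.null, logical(1))]
    new("SARunResult", aieNode = as.integer(aieNode),
        finalConformation = conf,
        finalEnergy = totalEnergy(conf, ligand, gcpGrid, lysGrid),
        levels = do.call(rbind, levels), terminatedBy = terminated)
  })
}

#' Ensemble of simulated-annealing runs
#'
#' `nRuns` independent runs with the AIE anchor drawn uniformly (with
#' replacement) from the placement layer. Per-run RNG seeds are derived
#' deterministically from the master seed, so results are bit-identical on
#' re-run and independent of execution order.
#'
#' @param nRuns Number of runs (production default 4000).
#' @param layer Integer `n x 3` matrix of candidate AIE nodes.
#' @param ligand [BeadSpringLigand-class].
#' @param gcpGrid,lysGrid Affinity grids.
#' @param mask Optional steric mask (see [simulatedAnnealing()]).
#' @param config [SAConfig-class]; its seed is the master seed.
#' @return List of [SARunResult-class], one per run.
#' @export
runEnsemble <- function(nRuns = 4000, layer, ligand, gcpGrid, lysGrid,
                        mask = NULL, config = saConfig()) {
  layer <- .asNodeMatrix(layer)
  if (nrow(layer) == 0) stop("empty placement layer")
  master <- if (is.na(config@seed)) {
    stats::runif(1, 1, 2^31 - 2)
  } else config@seed
  aieIdx <- .withSeed(floor(master) %% 2147483647,
                      sample.int(nrow(layer), nRuns, replace = TRUE))
  seeds <- ((floor(master) + seq_len(nRuns)) * 48271) %% 2147483647
  lapply(seq_len(nRuns), function(r) {
    cfg <- config
    cfg@seed <- seeds[r]
    simulatedAnnealing(layer[aieIdx[r], ], ligand, gcpGrid, lysGrid,
                       mask = mask, config = cfg)
  })
}
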