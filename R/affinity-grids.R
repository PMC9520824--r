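#' Ionic strength of a solvent
#'
#' `I = 1/2 sum c_i z_i^2` over all ionic species.
#'
#' @param solvent An [IonicSolvent-class].
#' @return Ionic strength in mol/L.
#' @examples
#' ionicStrength(referenceSolvent())  # 0.13 mol/L
#' @export
ionicStrength <- function(solvent) {
  stopifnot(is(solvent, "IonicSolvent"))
  s <- solvent@species
  if (!nrow(s)) return(0)
  0.5 * sum(s$concentration * s$valence^2)
}

#' Inverse Debye screening length
#'
#' Standard Debye-Hueckel closed form
#' `kappa^2 = 2 e^2 N_A (1000 I) / (eps0 epsW kB T)`, returned in 1/Angstrom.
#' Zero ionic strength gives `kappa = 0` (unscreened Coulomb).
#'
#' @param solvent An [IonicSolvent-class].
#' @return `kappa` in 1/Angstrom; the Debye length is `1/kappa`.
#' @examples
#' 1 / inverseDebyeLength(
#'   ionicSolvent(data.frame(concentration = c(0.1, 0.1), valence = c(1, -1)),
#'                temperature = 298))  # ~9.6 A
#' @export
inverseDebyeLength <- function(solvent) {
  I <- ionicStrength(solvent)
  if (I <= 0) return(0)
  e <- 1.602176634e-19       # C
  NA_ <- 6.02214076e23       # 1/mol
  eps0 <- 8.8541878128e-12   # F/m
  kBJ <- 1.380649e-23        # J/K
  kappaM <- sqrt(2 * e^2 * NA_ * 1000 * I /
                 (eps0 * solvent@epsWater * kBJ * solvent@temperature))
  kappaM * 1e-10             # 1/m -> 1/A
}

#' Screened-Coulomb (Debye-Hueckel) potential grid
#'
#' Superposition of per-atom screened Coulomb potentials:
#' `phi(x) = sum_i C q_i exp(-kappa * max(0, r_i - R_i)) / (epsW r_i)`,
#' with `C` the Coulomb constant in kJ A/(mol e^2). Screening is switched
#' off inside each atom's van der Waals radius `R_i`. Nodes closer than
#' 0.5 A to an atom center are clamped to the value at 0.5 A. This is a
#' fast, self-contained stand-in producing a potential on the same grid
#' geometry as a full Poisson-Boltzmann solve; it has no dielectric
#' boundary (`epsProtein` is unused) and no desolvation.
#'
#' @param protein A [ProteinStructure-class] (non-empty).
#' @param gridspec `list(origin=, spacing=, shape=)` or a [ScalarGrid-class]
#'   supplying the geometry.
#' @param solvent An [IonicSolvent-class].
#' @return A [ScalarGrid-class] of potential values, kJ/mol per |e|.
#' @export
dhPotentialGrid <- function(protein, gridspec, solvent = referenceSolvent()) {
  stopifnot(is(protein, "ProteinStructure"))
  if (nAtoms(protein) == 0) stop("empty structure: cannot compute potential")
  g <- .gridGeometry(gridspec)
  kappa <- inverseDebyeLength(solvent)
  a <- protein@atoms
  nodes <- nodeToCartesian(g, .allNodes(g$shape))
  phi <- numeric(nrow(nodes))
  chunk <- max(1L, floor(2e6 / nrow(nodes)))
  for (start in seq(1L, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(a))
    dx <- outer(nodes[, 1], a$x[rows], "-")
    dy <- outer(nodes[, 2], a$y[rows], "-")
    dz <- outer(nodes[, 3], a$z[rows], "-")
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    r[r < 0.5] <- 0.5
    scr <- if (kappa > 0) {
      exp(-kappa * pmax(0, sweep(r, 2, a$radius[rows], "-")))
    } else 1
    phi <- phi + as.vector((.COULOMB / solvent@epsWater) *
                           (scr / r) %*% a$charge[rows])
  }
  ScalarGrid(array(phi, dim = g$shape), origin = g$origin,
             spacing = g$spacing,
             forbidden = array(FALSE, dim = g$shape))
}

#' Steric mask of a protein on a grid
#'
#' A node is forbidden iff its center lies strictly inside some atom's
#' padded van der Waals sphere (`distance < radius + probePad`); a node
#' exactly at the radius is allowed.
#'
#' @param protein A [ProteinStructure-class].
#' @param gridspec Geometry (`list(origin=, spacing=, shape=)` or grid).
#' @param probePad Extra padding added to every atom radius, Angstrom.
#' @return A [ScalarGrid-class] with zero values and the mask in its
#'   forbidden slot.
#' @export
stericMask <- function(protein, gridspec, probePad = 0) {
  stopifnot(is(protein, "ProteinStructure"))
  g <- .gridGeometry(gridspec)
  a <- protein@atoms
  nodes <- nodeToCartesian(g, .allNodes(g$shape))
  forb <- logical(nrow(nodes))
  for (i in seq_len(nrow(a))) {
    d2 <- (nodes[, 1] - a$x[i])^2 + (nodes[, 2] - a$y[i])^2 +
          (nodes[, 3] - a$z[i])^2
    forb <- forb | d2 < (a$radius[i] + probePad)^2
  }
  ScalarGrid(array(0, dim = g$shape), origin = g$origin, spacing = g$spacing,
             forbidden = array(forb, dim = g$shape))
}

#' Quasi-uniform rotation set
#'
#' `n` rotation matrices drawn uniformly from SO(3) via random unit
#' quaternions (Shoemake's method), deterministic under a seed. `n = 1`
#' returns the identity rotation by convention.
#'
#' @param n Number of rotations (>= 1).
#' @param seed RNG seed (NULL/NA = current RNG state).
#' @return List of `3 x 3` rotation matrices.
#' @export
rotationSet <- function(n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(list(diag(3)))
  u <- .withSeed(seed, matrix(stats::runif(3 * n), ncol = 3))
  lapply(seq_len(n), function(i) {
    u1 <- u[i, 1]; u2 <- u[i, 2]; u3 <- u[i, 3]
    q <- c(sqrt(1 - u1) * sin(2 * pi * u2),
           sqrt(1 - u1) * cos(2 * pi * u2),
           sqrt(u1) * sin(2 * pi * u3),
           sqrt(u1) * cos(2 * pi * u3))
    w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  })
}

#' Electrostatic energy of a rigid probe at a node
#'
#' `sum_i q_i phi(node + R offset_i)` with trilinear interpolation of the
#' potential. Returns `+Inf` if any probe atom needs support from a
#' forbidden node or falls outside the grid.
#'
#' @param node Grid node (1-based triple) for the probe center.
#' @param rotation `3 x 3` rotation matrix applied to the probe offsets.
#' @param probe A [Probe-class].
#' @param potential A [ScalarGrid-class] of potential values (kJ/mol/|e|).
#' @param mask Optional [ScalarGrid-class] whose forbidden slot augments
#'   the potential grid's own mask.
#' @return Energy in kJ/mol (possibly `Inf`).
#' @export
probeEnergy <- function(node, rotation, probe, potential, mask = NULL) {
  grid <- .maskedPotential(potential, mask)
  center <- nodeToCartesian(grid, node)
  off <- as.matrix(probe@atoms[, c("dx", "dy", "dz")]) %*% t(rotation)
  pts <- sweep(off, 2, as.vector(center), "+")
  ip <- interpolateGrid(grid, pts)
  if (any(ip$blocked)) return(Inf)
  sum(probe@atoms$charge * ip$values)
}

.maskedPotential <- function(potential, mask) {
  stopifnot(is(potential, "ScalarGrid"))
  if (is.null(mask)) return(potential)
  stopifnot(is(mask, "ScalarGrid"))
  if (!.sameGeometry(potential, mask))
    stop("potential and mask grid geometries differ")
  potential@forbidden <- potential@forbidden | mask@forbidden
  potential
}

#' Rotational rigid-probe scan of a potential grid
#'
#' Evaluates the probe at every allowed node for each rotation and combines
#' the per-rotation energies per node: `mode = "min"` takes the minimum;
#' `mode = "boltzmann"` takes `-kB T log((1/N) sum_r exp(-E_r / kB T))`,
#' with infinite-energy rotations contributing zero weight. A node where
#' every rotation is infinite is forbidden in the output.
#'
#' @param potential [ScalarGrid-class] of the protein potential
#'   (kJ/mol/|e|).
#' @param mask Optional steric mask grid (same geometry).
#' @param probe A [Probe-class].
#' @param config A [ScanConfig-class].
#' @param rotations Optional explicit list of rotation matrices (overrides
#'   the config's rotation set); the result is invariant to their order.
#' @return An affinity [ScalarGrid-class] (kJ/mol).
#' @export
probeScan <- function(potential, mask, probe, config = scanConfig(),
                      rotations = NULL) {
  grid <- .maskedPotential(potential, mask)
  rots <- if (is.null(rotations)) {
    rotationSet(config@nRotations, config@seed)
  } else rotations
  shape <- dim(grid@values)
  nodes <- .allNodes(shape)
  centers <- nodeToCartesian(grid, nodes)
  nN <- nrow(nodes)
  q <- probe@atoms$charge
  off <- as.matrix(probe@atoms[, c("dx", "dy", "dz")])

  kT <- thermalEnergy(config@temperature)
  E <- matrix(NA_real_, nrow = nN, ncol = length(rots))
  for (rIdx in seq_along(rots)) {
    roff <- off %*% t(rots[[rIdx]])
    e <- numeric(nN)
    blocked <- logical(nN)
    for (aIdx in seq_len(nrow(roff))) {
      pts <- sweep(centers, 2, roff[aIdx, ], "+")
      ip <- interpolateGrid(grid, pts)
      blocked <- blocked | ip$blocked
      ok <- !blocked
      e[ok] <- e[ok] + q[aIdx] * ip$values[ok]
    }
    e[blocked] <- Inf
    E[, rIdx] <- e
  }
  vals <- if (config@mode == "boltzmann") {
    # stable log-mean-exp: shift by the per-node minimum
    m <- do.call(pmin, as.data.frame(E))
    out <- rep(Inf, nN)
    fin <- is.finite(m)
    if (any(fin)) {
      s <- rowSums(exp(-(E[fin, , drop = FALSE] - m[fin]) / kT))
      out[fin] <- m[fin] - kT * log(s / length(rots))
    }
    out
  } else {
    do.call(pmin, as.data.frame(E))
  }
  forb <- grid@forbidden | array(!is.finite(vals), dim = shape)
  vals[!is.finite(vals)] <- .INF_SENTINEL
  ScalarGrid(array(vals, dim = shape), origin = grid@origin,
             spacing = grid@spacing, forbidden = forb)
}
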