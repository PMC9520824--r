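# Non-bonded bead pairs of a 5-bead chain (1-based indices, |i-j| >= 2);
# bonded neighbors are exempt from the hard-core repulsion.
.NONBONDED_PAIRS <- rbind(c(1L, 3L), c(1L, 4L), c(1L, 5L),
                          c(2L, 4L), c(2L, 5L), c(3L, 5L))

#' The default five-bead ligand
#'
#' GCP-Lys-AIE-Lys-GCP chain with equilibrium spring lengths 6, 13, 13, 6 A
#' (GCP-Lys and Lys-AIE bonds), spring constants 12, 3, 3, 12 kBT/A^2
#' converted to kJ/(mol A^2) at `referenceT`, and a common hard-sphere
#' contact distance a = 9.6 A for all non-bonded pairs. The kBT-to-kJ/mol
#' conversion is done once at `referenceT`; the Hamiltonian does not
#' rescale with the annealing temperature.
#'
#' @param referenceT Reference temperature (K) for the unit conversion.
#' @return A [BeadSpringLigand-class].
#' @examples
#' lig <- defaultLigand()
#' lig@springConstants[1]  # 12 kBT/A^2 at 300 K ~ 29.93 kJ/(mol A^2)
#' @export
defaultLigand <- function(referenceT = 300) {
  stopifnot(referenceT > 0)
  kT <- thermalEnergy(referenceT)
  new("BeadSpringLigand",
      beadKinds = c("GCP", "Lys", "AIE", "Lys", "GCP"),
      springEqLengths = c(6, 13, 13, 6),
      springConstants = c(12, 3, 3, 12) * kT,
      hardCore = 9.6,
      referenceTemperature = referenceT)
}

#' Construct a conformation
#'
#' A conformation is a `5 x 3` integer matrix of 1-based grid node indices,
#' one row per bead in chain order (GCP, Lys, AIE, Lys, GCP); the AIE bead
#' is row 3.
#'
#' @param nodes `5 x 3` matrix (or length-15 vector, row-wise) of node
#'   indices.
#' @return An integer `5 x 3` matrix.
#' @export
conformation <- function(nodes) {
  if (is.null(dim(nodes))) nodes <- matrix(nodes, ncol = 3, byrow = TRUE)
  stopifnot(identical(dim(nodes), c(5L, 3L)) || identical(dim(nodes), c(5, 3)))
  storage.mode(nodes) <- "integer"
  dimnames(nodes) <- NULL
  nodes
}

#' Bond lengths of a conformation
#'
#' Euclidean distances between consecutive beads' Cartesian node centers.
#'
#' @param conf `5 x 3` node matrix (see [conformation()]).
#' @param grid Grid geometry ([ScalarGrid-class] or geometry list).
#' @return Numeric vector of four lengths, Angstrom.
#' @export
bondLengths <- function(conf, grid) {
  xyz <- nodeToCartesian(grid, conf)
  d <- xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Harmonic spring energy
#'
#' `1/2 sum_i k_i (l_i - l_i_eq)^2` over the four bonds.
#'
#' @param conf `5 x 3` node matrix.
#' @param ligand A [BeadSpringLigand-class].
#' @param grid Grid geometry.
#' @return Energy in kJ/mol.
#' @export
springEnergy <- function(conf, ligand, grid) {
  l <- bondLengths(conf, grid)
  0.5 * sum(ligand@springConstants * (l - ligand@springEqLengths)^2)
}

#' Hard-core feasibility
#'
#' TRUE iff every non-bonded bead pair is at distance `d >= a`
#' (the repelling potential is 0 at `d >= a` and infinite below); bonded
#' neighbors are exempt.
#'
#' @inheritParams springEnergy
#' @return Logical scalar.
#' @export
hardCoreOk <- function(conf, ligand, grid) {
  xyz <- nodeToCartesian(grid, conf)
  a2 <- ligand@hardCore^2
  p <- .NONBONDED_PAIRS
  d <- xyz[p[, 1], , drop = FALSE] - xyz[p[, 2], , drop = FALSE]
  all(rowSums(d * d) >= a2)
}

#' Grid (affinity) energy of a conformation
#'
#' Direct node lookup of the GCP affinity grid for the two terminal GCP
#' beads and the Lys grid for the two Lys beads; the AIE bead carries no
#' grid term. `+Inf` if any of the four beads is out of bounds or on a
#' forbidden node.
#'
#' @param conf `5 x 3` node matrix.
#' @param gcpGrid,lysGrid [ScalarGrid-class] affinity grids sharing one
#'   geometry.
#' @return Energy in kJ/mol (possibly `Inf`).
#' @export
gridEnergy <- function(conf, gcpGrid, lysGrid) {
  if (!.sameGeometry(gcpGrid, lysGrid))
    stop("gcpGrid and lysGrid geometries differ")
  shape <- dim(gcpGrid@values)
  beads <- c(1L, 2L, 4L, 5L)
  idx <- conf[beads, , drop = FALSE]
  if (!all(.inBounds(shape, idx))) return(Inf)
  total <- 0
  for (b in seq_along(beads)) {
    g <- if (beads[b] %in% c(1L, 5L)) gcpGrid else lysGrid
    i <- idx[b, ]
    if (g@forbidden[i[1], i[2], i[3]]) return(Inf)
    total <- total + g@values[i[1], i[2], i[3]]
  }
  total
}

#' Total energy of a conformation
#'
#' Hard-core status is evaluated first: `+Inf` if any non-bonded pair
#' overlaps or any grid-coupled bead sits on a forbidden/out-of-bounds
#' node; otherwise spring energy plus grid energy.
#'
#' @inheritParams gridEnergy
#' @param ligand A [BeadSpringLigand-class].
#' @return Energy in kJ/mol (possibly `Inf`).
#' @export
totalEnergy <- function(conf, ligand, gcpGrid, lysGrid) {
  if (!hardCoreOk(conf, ligand, gcpGrid)) return(Inf)
  g <- gridEnergy(conf, gcpGrid, lysGrid)
  if (!is.finite(g)) return(Inf)
  springEnergy(conf, ligand, gcpGrid) + g
}
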